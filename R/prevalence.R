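# Mutation-class filtering, antigen-presentation-machinery (APM) mutant
# calls, pathway prevalence tables, and cross-study enrichment-frequency
# aggregation used to pick core immunomodulatory pathways.

#' Variant classifications counted as non-synonymous
#' @export
NONSYNONYMOUS_CLASSES <- c(
  "Frame_Shift_Del", "Frame_Shift_Ins", "Splice_Site",
  "Translation_Start_Site", "Nonsense_Mutation", "Nonstop_Mutation",
  "In_Frame_Del", "In_Frame_Ins", "Missense_Mutation")

# Known synonymous / non-coding labels; anything outside either list is
# unknown and triggers a warning (treated as not non-synonymous).
SYNONYMOUS_CLASSES <- c(
  "Silent", "Synonymous", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "Intron",
  "IGR", "RNA", "Splice_Region", "lincRNA", "Targeted_Region")

#' Antigen presentation machinery genes whose point mutations define an
#' APM mutant (HLA-A/B/C are handled through the LOH route, not this list).
#' @export
APM_GENES <- c("B2M", "NLRC5", "PSMB8", "PSMB9", "PSMB10", "ERAP1", "ERAP2",
               "TAP1", "TAP2", "TAPBP")

#' Is a variant classification non-synonymous?
#'
#' @param classification Character vector of variant classifications.
#' @return Logical vector; labels outside the controlled vocabulary return
#'   FALSE and raise one warning with the unknown-label count.
#' @export
is_nonsynonymous <- function(classification) {
  known <- c(NONSYNONYMOUS_CLASSES, SYNONYMOUS_CLASSES)
  unknown <- !is.na(classification) & !(classification %in% known)
  if (any(unknown))
    warning(sum(unknown), " mutation(s) with unknown classification label(s) (",
            paste(unique(classification[unknown]), collapse = ", "),
            ") treated as not non-synonymous")
  classification %in% NONSYNONYMOUS_CLASSES
}

#' Call a sample APM-mutant
#'
#' A sample is an APM mutant iff it has HLA LOH or at least one
#' non-synonymous point mutation in an APM gene.
#'
#' @param mutations data.frame with `gene`, `variant_classification` for one
#'   sample (may have 0 rows).
#' @param has_hla_loh Logical: any HLA LOH call in the sample.
#' @param apm_genes APM gene set (default [APM_GENES]).
#' @return Logical scalar.
#' @export
apm_mutant_call <- function(mutations, has_hla_loh, apm_genes = APM_GENES) {
  apm_snv <- FALSE
  if (nrow(mutations))
    apm_snv <- any(is_nonsynonymous(mutations$variant_classification) &
                     .norm_gene(mutations$gene) %in% .norm_gene(apm_genes))
  isTRUE(has_hla_loh) || apm_snv
}

.norm_gene <- function(g) toupper(trimws(g))

#' Sample-by-pathway mutation matrix and prevalence fractions
#'
#' A sample is pathway-mutant iff it carries at least one non-synonymous
#' mutation in the pathway's genes. Duplicate (sample, gene, pos) rows are
#' collapsed first; genes in no set are tallied in a leftover report.
#'
#' @param mutations data.frame with `sample`, `gene`,
#'   `variant_classification`, optionally `pos` and `cancer_type`.
#' @param gene_sets Named list of gene vectors.
#' @param cancer_types Optional data.frame `sample`, `cancer_type`
#'   (overrides a `cancer_type` column); also supplies samples with zero
#'   mutations so denominators are cohort sizes, not mutated-sample counts.
#' @param filter_nonsynonymous Apply the class filter internally (default
#'   TRUE; set FALSE if already applied).
#' @return List: `matrix` (logical samples x pathways), `prevalence`
#'   (data.frame `cancer_type`, `pathway`, `n_mutant`, `n_samples`,
#'   `prevalence`; includes an "all" row per pathway), `leftover_genes`
#'   (mutated genes in no set, with counts).
#' @export
prevalence_table <- function(mutations, gene_sets, cancer_types = NULL,
                             filter_nonsynonymous = TRUE) {
  mutations <- as.data.frame(mutations, stringsAsFactors = FALSE)
  if (filter_nonsynonymous && nrow(mutations))
    mutations <- mutations[is_nonsynonymous(mutations$variant_classification), ,
                           drop = FALSE]
  keycols <- intersect(c("sample", "gene", "pos"), names(mutations))
  if (nrow(mutations))
    mutations <- mutations[!duplicated(mutations[, keycols, drop = FALSE]), ,
                           drop = FALSE]
  if (!is.null(cancer_types)) {
    samples <- cancer_types$sample
    ct <- cancer_types$cancer_type
  } else if ("cancer_type" %in% names(mutations)) {
    u <- unique(mutations[, c("sample", "cancer_type")])
    samples <- u$sample; ct <- u$cancer_type
  } else {
    samples <- unique(mutations$sample); ct <- rep("all", length(samples))
  }
  mat <- matrix(FALSE, length(samples), length(gene_sets),
                dimnames = list(samples, names(gene_sets)))
  in_any <- rep(FALSE, nrow(mutations))
  for (p in names(gene_sets)) {
    hit <- .norm_gene(mutations$gene) %in% .norm_gene(gene_sets[[p]])
    in_any <- in_any | hit
    hs <- unique(mutations$sample[hit])
    mat[match(intersect(hs, samples), samples), p] <- TRUE
  }
  leftover <- if (any(!in_any))
    as.data.frame(table(gene = mutations$gene[!in_any]),
                  stringsAsFactors = FALSE)
  else data.frame(gene = character(), Freq = integer())
  groups <- c(list(all = seq_along(samples)),
              split(seq_along(samples), ct))
  prev <- do.call(rbind, lapply(names(groups), function(g) {
    idx <- groups[[g]]
    data.frame(cancer_type = g, pathway = names(gene_sets),
               n_mutant = colSums(mat[idx, , drop = FALSE]),
               n_samples = length(idx),
               prevalence = colSums(mat[idx, , drop = FALSE]) / length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(prev) <- NULL
  list(matrix = mat, prevalence = prev, leftover_genes = leftover)
}

#' Select the top-ranked regulators in one direction
#'
#' @param ranked data.frame already ranked by the study's score, with
#'   columns `gene` and `direction` ("positive"/"negative").
#' @param n Number of genes to take (default 100).
#' @param direction Which direction to select.
#' @return Character vector of up to `n` genes (warns when fewer exist).
#' @export
select_top_regulators <- function(ranked, n = 100L,
                                  direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (!"direction" %in% names(ranked)) stop("ranked table lacks a 'direction' column")
  g <- ranked$gene[ranked$direction == direction]
  if (n == 0L) return(character(0))
  if (length(g) < n)
    warning("only ", length(g), " ", direction, " regulators available (asked for ", n, ")")
  utils::head(g, n)
}

#' Rank pathways by how many studies report them enriched
#'
#' @param study_tables Named list of per-study data.frames, each with
#'   `pathway` and `adj_p` (already thresholded upstream, e.g. adj_p < 0.1).
#' @return data.frame `pathway`, `n_studies`, `best_adj_p`, ranked by
#'   descending study count, then smallest adjusted p, then pathway name.
#'   A single-study category is passed through with attribute
#'   `single_study = TRUE`.
#' @export
enrichment_frequency <- function(study_tables) {
  if (!length(study_tables))
    return(structure(data.frame(pathway = character(), n_studies = integer(),
                                best_adj_p = numeric()), single_study = FALSE))
  all <- do.call(rbind, lapply(names(study_tables), function(s) {
    t <- study_tables[[s]]
    if (!nrow(t)) return(NULL)
    data.frame(study = s, pathway = t$pathway, adj_p = t$adj_p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all))
    return(structure(data.frame(pathway = character(), n_studies = integer(),
                                best_adj_p = numeric()),
                     single_study = length(study_tables) == 1L))
  sp <- split(all, all$pathway)
  out <- do.call(rbind, lapply(sp, function(g)
    data.frame(pathway = g$pathway[1L],
               n_studies = length(unique(g$study)),
               best_adj_p = min(g$adj_p), stringsAsFactors = FALSE)))
  out <- out[order(-out$n_studies, out$best_adj_p, out$pathway), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, single_study = length(study_tables) == 1L)
}

#' Read / write gene sets in GMT format
#'
#' Standard tab-separated GMT: set name, description, then gene symbols.
#'
#' @param path File path.
#' @param gene_sets Named list of gene vectors (writer).
#' @param descriptions Optional named descriptions (writer).
#' @return Named list of gene vectors (reader); `path` invisibly (writer).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) stop("malformed GMT line: ", substr(ln, 1, 60))
    out[[parts[1L]]] <- parts[-(1:2)]
  }
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path, descriptions = NULL) {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "na", gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
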