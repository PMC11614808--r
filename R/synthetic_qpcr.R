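#' Design of a synthetic qPCR experiment
#'
#' Describes the Ct-generating model used by [generate_qpcr()]:
#' `Ct(sample, gene) = baseline_ct[gene] - programmed_log2_fold(gene, group)
#' - loading_offset(sample) + technical noise`. The loading offset is shared
#' by every gene of a sample (including the reference), which is exactly what
#' the delta-Ct normalization cancels. Replicates whose noiseless Ct exceeds
#' the cycle limit (40 cycles, the run length of the assay) are flagged
#' non-detect, as is an optional random dropout.
#'
#' @param genes character vector of assayed genes; must include the
#'   reference gene.
#' @param reference_gene reference (housekeeping) gene name, default "18s".
#' @param groups data.frame with columns `line`, `treatment`, `dpi` (one row
#'   per experimental group, e.g. lines mpeg1:FP / mpeg1:myd88, treatments
#'   saline / ouabain, days post injection).
#' @param n_biological biological replicates (retinas) per group.
#' @param n_technical technical replicates per (sample, gene).
#' @param baseline_ct named numeric: mean Ct of each gene in the calibrator
#'   condition.
#' @param programmed_log2_fold data.frame with columns `gene`, `line`,
#'   `treatment`, `dpi`, `log2_fold`: programmed log2 expression change
#'   relative to the matched saline group. Unlisted combinations are 0. The
#'   reference gene must have fold 0 everywhere.
#' @param ct_noise_sd technical Ct noise (cycles).
#' @param reference_drift_sd sd of the per-sample loading offset (cycles);
#'   this is what makes raw reference-gene Ct drift between samples. The
#'   default 0.1 reproduces a stable reference whose inter-sample range
#'   stays within ~1-1.4 on the fold scale across a few dozen samples.
#' @param nondetect_ct_limit amplification cycle limit (default 40).
#' @param dropout_prob extra probability that a technical replicate fails.
#' @param seed design seed.
#' @return a `qpcr_design` list.
#' @export
qpcr_design <- function(genes = c("18s", "ascl1a", "lin28a"),
                        reference_gene = "18s",
                        groups = expand.grid(
                          line = c("mpeg1:FP", "mpeg1:myd88"),
                          treatment = c("saline", "ouabain"),
                          dpi = 4L, stringsAsFactors = FALSE),
                        n_biological = 6L, n_technical = 3L,
                        baseline_ct = c("18s" = 12, "ascl1a" = 26,
                                        "lin28a" = 30),
                        programmed_log2_fold = NULL,
                        ct_noise_sd = 0.15, reference_drift_sd = 0.1,
                        nondetect_ct_limit = 40, dropout_prob = 0,
                        seed = 1L) {
  if (!reference_gene %in% genes)
    stop_retinaquant(paste0("reference gene '", reference_gene,
                            "' missing from genes"),
                     "qpcr_config_error")
  if (!all(genes %in% names(baseline_ct)))
    stop_retinaquant("baseline_ct must name every gene", "qpcr_config_error")
  if (ct_noise_sd < 0 || reference_drift_sd < 0)
    stop_retinaquant("noise sds must be >= 0", "qpcr_config_error")
  if (is.null(programmed_log2_fold))
    programmed_log2_fold <- data.frame(gene = character(0),
                                       line = character(0),
                                       treatment = character(0),
                                       dpi = integer(0),
                                       log2_fold = numeric(0))
  if (any(programmed_log2_fold$gene == reference_gene &
          programmed_log2_fold$log2_fold != 0))
    stop_retinaquant("reference gene must have programmed fold 0",
                     "qpcr_config_error")
  structure(list(genes = genes, reference_gene = reference_gene,
                 groups = groups, n_biological = as.integer(n_biological),
                 n_technical = as.integer(n_technical),
                 baseline_ct = baseline_ct,
                 programmed_log2_fold = programmed_log2_fold,
                 ct_noise_sd = ct_noise_sd,
                 reference_drift_sd = reference_drift_sd,
                 nondetect_ct_limit = nondetect_ct_limit,
                 dropout_prob = dropout_prob, seed = as.integer(seed)),
            class = "qpcr_design")
}

.lookup_fold <- function(design, gene, line, treatment, dpi) {
  f <- design$programmed_log2_fold
  hit <- f$gene == gene & f$line == line & f$treatment == treatment &
    f$dpi == dpi
  if (any(hit)) f$log2_fold[which(hit)[1]] else 0
}

#' Generate a replicate-level Ct table from a design
#'
#' One biological sample corresponds to one retina; every gene of a sample
#' shares the sample's loading offset so that delta-Ct cancels it exactly.
#'
#' @param design a [qpcr_design()].
#' @return a `ct_table` data.frame with columns `sample_id`, `line`,
#'   `treatment`, `dpi`, `gene`, `tech_rep`, `ct`, `nondetect`.
#' @export
generate_qpcr <- function(design) {
  stopifnot(inherits(design, "qpcr_design"))
  with_seed(design$seed, .generate_qpcr_impl(design))
}

.generate_qpcr_impl <- function(d) {
  rows <- list()
  for (g in seq_len(nrow(d$groups))) {
    grp <- d$groups[g, ]
    for (b in seq_len(d$n_biological)) {
      sample_id <- sprintf("%s_%s_%ddpi_r%02d",
                           gsub("[^A-Za-z0-9]", "", grp$line),
                           grp$treatment, grp$dpi, b)
      loading <- rnorm(1, 0, d$reference_drift_sd)
      for (gene in d$genes) {
        l2f <- .lookup_fold(d, gene, grp$line, grp$treatment, grp$dpi)
        ct_true <- d$baseline_ct[[gene]] - l2f - loading
        for (tr in seq_len(d$n_technical)) {
          ct <- ct_true + rnorm(1, 0, d$ct_noise_sd)
          nd <- ct_true > d$nondetect_ct_limit ||
            (d$dropout_prob > 0 && runif(1) < d$dropout_prob)
          rows[[length(rows) + 1]] <- data.frame(
            sample_id = sample_id, line = grp$line,
            treatment = grp$treatment, dpi = grp$dpi, gene = gene,
            tech_rep = tr, ct = if (nd) NA_real_ else ct,
            nondetect = nd)
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ct_table", "data.frame")
  out
}

#' Read/write Ct tables as CSV
#' @param table a `ct_table` data.frame.
#' @param path CSV path.
#' @export
write_ct_table <- function(table, path) {
  write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ct_table
#' @export
read_ct_table <- function(path) {
  t <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "line", "treatment", "dpi", "gene", "tech_rep",
            "ct", "nondetect")
  miss <- setdiff(need, names(t))
  if (length(miss) > 0)
    stop_retinaquant(paste0("ct table missing columns: ",
                            paste(miss, collapse = ", ")),
                     "qpcr_config_error")
  t$nondetect <- as.logical(t$nondetect)
  class(t) <- c("ct_table", "data.frame")
  t
}
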