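#' Generate a synthetic neoantigen fixture panel
#'
#' Two panel shapes are provided, matching the study systems:
#' \describe{
#'   \item{bbn963}{34 neoantigens with nonnegative synthetic ELISpot-like
#'     scores (most zero or low, a few high, so that after min-max scaling
#'     only a handful carry substantial immunogenicity) and one of two MHC
#'     alleles.}
#'   \item{mc38}{489 neoantigens with R resampled from the bbn963-like
#'     empirical immunogenicity distribution and one of two MHC alleles.}
#' }
#' Generation is deterministic given the seed.
#'
#' @param kind `"bbn963"` or `"mc38"`.
#' @param seed integer seed.
#' @return data.frame: `id`, `elispot_score` (bbn963 only), `R`,
#'   `mhc_allele` (0-based).
#' @export
generate_fixture <- function(kind = c("bbn963", "mc38"), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  base <- local({
    n <- 34L
    grp <- sample(c("zero", "low", "high"), n, replace = TRUE,
                  prob = c(0.55, 0.36, 0.09))
    score <- numeric(n)
    score[grp == "low"] <- round(stats::rlnorm(sum(grp == "low"),
                                               meanlog = log(8), sdlog = 0.8), 1)
    score[grp == "high"] <- round(stats::rlnorm(sum(grp == "high"),
                                                meanlog = log(120), sdlog = 0.4), 1)
    if (all(score == 0)) score[1] <- 100  # guard: degenerate draw
    data.frame(id = seq_len(n), elispot_score = score,
               R = elispot_to_immunogenicity(score),
               mhc_allele = sample(0:1, n, replace = TRUE))
  })
  if (kind == "bbn963") return(base)
  n <- 489L
  data.frame(id = seq_len(n),
             R = sample(base$R, n, replace = TRUE),
             mhc_allele = sample(0:1, n, replace = TRUE))
}

#' Read or write a neoantigen panel (CSV/TSV)
#'
#' Panels are tabular files with a header and columns `id`, `mhc_allele`
#' (0-based) and either `R` or `elispot_score` (scores are min-max scaled to
#' R on read). Optional feature columns (`affinity_nM`, `stability_h`,
#' `agretopicity`, `tpm`, `foreignness`) are passed through.
#'
#' @param path file path (`.csv` or `.tsv`).
#' @param panel panel data.frame.
#' @return `read_panel`: data.frame with an `R` column; `write_panel`: the
#'   path, invisibly.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  panel <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE)
  if (nrow(panel) == 0) stop("empty panel file: ", path)
  need <- c("id", "mhc_allele")
  miss <- setdiff(need, names(panel))
  if (length(miss))
    stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (!"R" %in% names(panel)) {
    if (!"elispot_score" %in% names(panel))
      stop("panel needs an 'R' or 'elispot_score' column")
    panel$R <- elispot_to_immunogenicity(panel$elispot_score)
  }
  panel
}

#' @rdname read_panel
#' @export
write_panel <- function(panel, path) {
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(panel, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
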