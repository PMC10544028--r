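#' Assemble a table of IDR records
#'
#' @param ids character identifiers.
#' @param sequences amino-acid strings (20-letter alphabet).
#' @param scores optional per-record mean disorder scores in `[0, 1]`.
#' @return data.frame with columns `id`, `sequence`, `score`.
#' @export
idr_records <- function(ids, sequences, scores = NULL) {
  stopifnot(length(ids) == length(sequences),
            all(nzchar(sequences)))
  if (is.null(scores)) scores <- rep(NA_real_, length(ids))
  stopifnot(length(scores) == length(ids))
  data.frame(id = as.character(ids), sequence = as.character(sequences),
             score = as.numeric(scores), stringsAsFactors = FALSE)
}

#' Read IDR sequences from FASTA, optionally joining disorder scores
#'
#' Scores arrive precomputed (e.g. from a disorder predictor) in a
#' two-column tab-separated file `id <TAB> score`, joined by id; running a
#' predictor is out of scope for this package.
#'
#' @param path FASTA of amino-acid sequences.
#' @param score_path optional TSV with columns id, score (no header
#'   required; a `id\tscore` header line is tolerated).
#' @return data.frame as from [idr_records()].
#' @export
read_idr_fasta <- function(path, score_path = NULL) {
  set <- Biostrings::readAAStringSet(path)
  rec <- idr_records(names(set), as.character(set))
  if (!is.null(score_path)) {
    sc <- utils::read.table(score_path, sep = "\t", header = FALSE,
                            col.names = c("id", "score"),
                            stringsAsFactors = FALSE)
    if (identical(sc$id[1], "id")) sc <- sc[-1, ]
    sc$score <- as.numeric(sc$score)
    rec$score <- sc$score[match(rec$id, sc$id)]
  }
  rec
}

#' Filter IDR records by length and disorder score
#'
#' Keeps records of at least `min_length` residues whose disorder score is
#' strictly greater than `score_threshold` (a record scoring exactly at the
#' threshold is excluded). Records without scores pass the score filter only
#' when `require_scores = FALSE`.
#'
#' @param records data.frame from [idr_records()] / [read_idr_fasta()].
#' @param min_length minimum sequence length (default 50).
#' @param score_threshold disorder score cut (default 0.5, strict).
#' @param require_scores logical; drop score-less records (default TRUE).
#' @return the filtered data.frame.
#' @export
filter_idrs <- function(records, min_length = 50, score_threshold = 0.5,
                        require_scores = TRUE) {
  len_ok <- nchar(records$sequence) >= min_length
  sc <- records$score
  score_ok <- ifelse(is.na(sc), !require_scores, sc > score_threshold)
  records[len_ok & score_ok, , drop = FALSE]
}

#' Charge and aromatic fractions of one amino-acid sequence
#'
#' @param sequence amino-acid string (classified via [classify_sequence()]).
#' @return named numeric vector `c(f_plus, f_minus, phi)` — counts of
#'   positive, negative and aromatic residues over the full length.
#' @export
sequence_fractions <- function(sequence) {
  seq <- classify_sequence(sequence)
  fr <- compute_fractions(seq)
  c(f_plus = fr$f_plus, f_minus = fr$f_minus, phi = fr$phi)
}

#' Bin IDRs by aromatic content and fit the charge-fraction trends
#'
#' Computes per-sequence `(f_plus, f_minus, phi)`, bins sequences by phi
#' (non-overlapping bins of width `bin_width` tiling `[0, 1]`), drops bins
#' with fewer than `min_bin_n` members, and fits ordinary least squares of
#' the bin-mean charge fractions against bin centres — one fit for `f_plus`
#' and one for `f_minus`. Fits are unweighted by default (a binned-scatter
#' reading); `weighted = TRUE` weights bins by occupancy.
#'
#' @param records filtered IDR data.frame.
#' @param bin_width phi bin width (default 0.05).
#' @param min_bin_n smallest bin occupancy retained (default 10).
#' @param weighted logical; weight bins by member count.
#' @return a `idr_charge_fit`: `bins` data.frame (centre, width, mean_f_plus,
#'   mean_f_minus, n), `fit_plus`, `fit_minus` (both `lm`), and `coef`
#'   helpers via [coef.idr_charge_fit()].
#' @export
bin_and_fit <- function(records, bin_width = 0.05, min_bin_n = 10,
                        weighted = FALSE) {
  fr <- t(vapply(records$sequence, sequence_fractions, numeric(3)))
  rownames(fr) <- NULL
  bin_idx <- as.integer(pmin(floor(fr[, "phi"] / bin_width),
                             ceiling(1 / bin_width) - 1))
  idx_levels <- sort(unique(bin_idx))
  bins <- data.frame(
    centre = (idx_levels + 0.5) * bin_width,
    f_plus = as.vector(tapply(fr[, "f_plus"], bin_idx, mean)),
    f_minus = as.vector(tapply(fr[, "f_minus"], bin_idx, mean)),
    n = as.vector(tapply(bin_idx, bin_idx, length)))
  bins <- bins[bins$n >= min_bin_n, ]
  if (nrow(bins) < 2) {
    stop("fewer than 2 populated phi bins: cannot fit linear trends")
  }
  w <- if (weighted) bins$n else NULL
  fit_plus <- stats::lm(f_plus ~ centre, data = bins, weights = w)
  fit_minus <- stats::lm(f_minus ~ centre, data = bins, weights = w)
  bins$width <- bin_width
  structure(list(bins = bins, fit_plus = fit_plus, fit_minus = fit_minus,
                 weighted = weighted, n_records = nrow(records)),
            class = "idr_charge_fit")
}

#' @export
print.idr_charge_fit <- function(x, ...) {
  cp <- stats::coef(x$fit_plus); cm <- stats::coef(x$fit_minus)
  cat("<idr_charge_fit> on", nrow(x$bins), "phi bins (",
      x$n_records, "sequences )\n")
  cat(sprintf("  f+ = %.3f %+.3f phi\n", cp[1], cp[2]))
  cat(sprintf("  f- = %.3f %+.3f phi\n", cm[1], cm[2]))
  invisible(x)
}

#' @export
coef.idr_charge_fit <- function(object, ...) {
  cp <- stats::coef(object$fit_plus); cm <- stats::coef(object$fit_minus)
  c(intercept_plus = unname(cp[1]), slope_plus = unname(cp[2]),
    intercept_minus = unname(cm[1]), slope_minus = unname(cm[2]))
}

#' @export
plot.idr_charge_fit <- function(x, ...) {
  b <- x$bins
  graphics::plot(b$centre, b$f_plus, col = "blue", pch = 16,
                 ylim = range(c(b$f_plus, b$f_minus)),
                 xlab = expression(phi), ylab = "mean charge fraction", ...)
  graphics::points(b$centre, b$f_minus, col = "red", pch = 16)
  graphics::abline(x$fit_plus, col = "blue")
  graphics::abline(x$fit_minus, col = "red")
  graphics::legend("topright", c("f+", "f-"), col = c("blue", "red"),
                   pch = 16, bty = "n")
  invisible(x)
}

# regime-specific linear relations between phi and expected charge fractions
idr_regimes <- list(
  proteome = list(plus = c(0.13, -0.28), minus = c(0.145, -0.13),
                  phi_max = 0.30),
  llps = list(plus = c(0.13, -0.39), minus = c(0.17, -1.05),
              phi_max = 0.15))

#' Generate a synthetic IDR set with prescribed charge-vs-aromatic trends
#'
#' Emulates the two observed regimes of disordered regions: the proteome-wide
#' regime (`f+ = 0.13 - 0.28 phi`, `f- = 0.145 - 0.13 phi`) and the
#' LLPS-prone regime (`f+ = 0.13 - 0.39 phi`, `f- = 0.17 - 1.05 phi`, whose
#' steeper f- decay yields aromatic-rich sequences of net positive charge).
#' Per record, phi is drawn uniformly from `[0, phi_max)` (regime default
#' keeps both expected fractions positive), the aromatic count is set to
#' `round(phi * length)`, and the charge counts are binomial draws at the
#' linear relations evaluated at the realized aromatic fraction — so the
#' prescribed lines hold conditionally on the realized phi, which is exactly
#' the relation the binned analysis estimates from sequences. A shuffled
#' sequence of that composition is emitted (K/D for charges, F aromatic,
#' G/S/A/P/Q/N neutral). Deterministic for a fixed seed. Every record
#' carries disorder score 1.
#'
#' @param n number of records (>= 1).
#' @param regime `"proteome"` or `"llps"`.
#' @param seed integer seed.
#' @param phi_max upper end of the phi distribution (regime default if
#'   `NULL`).
#' @param length_range integer range of sequence lengths (uniform draw),
#'   minimum 50.
#' @return data.frame as from [idr_records()].
#' @export
synthesize_idr_set <- function(n, regime = c("proteome", "llps"), seed = 1L,
                               phi_max = NULL, length_range = c(50, 300)) {
  regime <- match.arg(regime)
  stopifnot(n >= 1, length_range[1] >= 50)
  rg <- idr_regimes[[regime]]
  if (is.null(phi_max)) phi_max <- rg$phi_max
  set.seed(seed)
  neutrals <- c("G", "S", "A", "P", "Q", "N")
  seqs <- character(n)
  for (i in seq_len(n)) {
    phi <- stats::runif(1, 0, phi_max)
    len <- sample(length_range[1]:length_range[2], 1)
    n_a <- round(phi * len)
    phi_r <- n_a / len
    fp <- max(0, rg$plus[1] + rg$plus[2] * phi_r)
    fm <- max(0, rg$minus[1] + rg$minus[2] * phi_r)
    n_p <- stats::rbinom(1, len, fp)
    n_m <- stats::rbinom(1, len, fm)
    while (n_a + n_p + n_m > len) {  # vanishingly rare at these fractions
      n_p <- stats::rbinom(1, len, fp)
      n_m <- stats::rbinom(1, len, fm)
    }
    res <- c(rep("K", n_p), rep("D", n_m), rep("F", n_a),
             sample(neutrals, len - n_a - n_p - n_m, replace = TRUE))
    seqs[i] <- paste(sample(res), collapse = "")
  }
  idr_records(sprintf("%s_%05d", regime, seq_len(n)), seqs,
              scores = rep(1, n))
}
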