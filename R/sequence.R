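#' @useDynLib cgphase, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Bead classes of the coarse alphabet. NEU only arises when classifying
# 20-letter sequences; designed sequences use the three interacting classes.
CG_CLASSES <- c("POS", "NEG", "ARO", "NEU")

# one-letter encoding used for FASTA round-trips of coarse sequences
CG_ENCODE <- c(POS = "K", NEG = "E", ARO = "F", NEU = "G")

#' Construct a coarse-grained peptide sequence
#'
#' A `cg_sequence` is an ordered vector of bead classes over
#' `{POS, NEG, ARO, NEU}`: positively charged, negatively charged, aromatic,
#' and (for classified natural sequences) neutral beads. All patterning
#' metrics, the sequence designer and the simulation engine operate on this
#' representation.
#'
#' @param residues character vector of class labels (`"POS"`, `"NEG"`,
#'   `"ARO"`, `"NEU"`), or a single string over the one-letter coarse
#'   encoding K/E/F (plus G for neutral).
#' @param id free-text identifier carried through outputs.
#' @return an object of class `cg_sequence`.
#' @examples
#' s <- coarse_sequence(rep(c("POS", "NEG"), 10))
#' net_charge(s)
#' @export
coarse_sequence <- function(residues, id = "seq") {
  if (is.character(residues) && length(residues) == 1L &&
      !residues[1] %in% CG_CLASSES) {
    letters1 <- strsplit(residues, "")[[1]]
    dec <- names(CG_ENCODE)[match(toupper(letters1), CG_ENCODE)]
    if (anyNA(dec)) {
      stop("unrecognised coarse-encoding letter at position ",
           which(is.na(dec))[1])
    }
    residues <- dec
  }
  residues <- as.character(residues)
  if (length(residues) < 1L) stop("sequence must have length >= 1")
  bad <- which(!residues %in% CG_CLASSES)
  if (length(bad)) {
    stop("unknown residue class at position ", bad[1], ": ", residues[bad[1]])
  }
  structure(list(residues = residues, length = length(residues), id = id),
            class = "cg_sequence")
}

#' @export
print.cg_sequence <- function(x, ...) {
  cat("<cg_sequence> ", x$id, " (", x$length, " residues)\n", sep = "")
  cat(" ", paste(CG_ENCODE[x$residues], collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
as.character.cg_sequence <- function(x, ...) {
  paste(CG_ENCODE[x$residues], collapse = "")
}

#' @export
length.cg_sequence <- function(x) x$length

#' Classify a 20-letter amino-acid sequence into coarse bead classes
#'
#' Lysine and arginine map to `POS`, aspartate and glutamate to `NEG`,
#' phenylalanine/tyrosine/tryptophan to `ARO`; every other standard residue
#' (including histidine, whose protonation is not modelled) maps to `NEU`.
#' Neutral beads carry zero charge and are ignored by the FCR and phi
#' numerators but count in the length denominator.
#'
#' @param aa_sequence single string of standard amino-acid one-letter codes
#'   (case-insensitive).
#' @param id identifier for the resulting sequence.
#' @return a `cg_sequence` (possibly containing `NEU` beads).
#' @examples
#' classify_sequence("KRDEFYW")
#' @export
classify_sequence <- function(aa_sequence, id = "seq") {
  stopifnot(is.character(aa_sequence), length(aa_sequence) == 1L,
            nzchar(aa_sequence))
  aa <- strsplit(toupper(aa_sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  bad <- which(!aa %in% valid)
  if (length(bad)) {
    stop("invalid amino-acid letter '", aa[bad[1]], "' at position ", bad[1])
  }
  cls <- rep("NEU", length(aa))
  cls[aa %in% c("K", "R")] <- "POS"
  cls[aa %in% c("D", "E")] <- "NEG"
  cls[aa %in% c("F", "Y", "W")] <- "ARO"
  coarse_sequence(cls, id = id)
}

# signed charges of a cg_sequence (+1 / -1 / 0)
sequence_charges <- function(seq) {
  q <- integer(seq$length)
  q[seq$residues == "POS"] <- 1L
  q[seq$residues == "NEG"] <- -1L
  q
}

#' Net charge of a coarse sequence
#' @param seq a `cg_sequence`.
#' @return integer, number of POS minus number of NEG beads.
#' @export
net_charge <- function(seq) {
  stopifnot(inherits(seq, "cg_sequence"))
  sum(sequence_charges(seq))
}

#' Composition fractions of a coarse sequence
#'
#' Computes the fraction of charged residues (FCR), aromatic content (phi),
#' the separate positive and negative fractions and the net charge. On the
#' pure 3-letter alphabet `fcr + phi = 1`; classified natural sequences also
#' carry neutral beads, so the identity then no longer holds.
#'
#' @param seq a `cg_sequence`.
#' @return named list with `fcr`, `phi`, `f_plus`, `f_minus`, `net_charge`.
#' @examples
#' compute_fractions(coarse_sequence(c(rep("POS", 2), rep("ARO", 2))))
#' @export
compute_fractions <- function(seq) {
  stopifnot(inherits(seq, "cg_sequence"))
  n <- seq$length
  f_plus <- sum(seq$residues == "POS") / n
  f_minus <- sum(seq$residues == "NEG") / n
  list(fcr = f_plus + f_minus,
       phi = sum(seq$residues == "ARO") / n,
       f_plus = f_plus,
       f_minus = f_minus,
       net_charge = net_charge(seq))
}

# delta_g statistic of the Das-Pappu kappa for one blob size:
# mean over overlapping windows of (sigma_blob - sigma_seq)^2, where
# sigma = (f+ - f-)^2 / (f+ + f-), taken as 0 for windows with no charges.
kappa_delta <- function(q, g) {
  n <- length(q)
  pos <- cumsum(c(0L, q == 1L))
  neg <- cumsum(c(0L, q == -1L))
  i <- seq_len(n - g + 1L)
  np <- pos[i + g] - pos[i]
  nm <- neg[i + g] - neg[i]
  fp <- np / g
  fm <- nm / g
  tot <- fp + fm
  sig <- ifelse(tot > 0, (fp - fm)^2 / tot, 0)
  np_all <- sum(q == 1L); nm_all <- sum(q == -1L)
  fps <- np_all / n; fms <- nm_all / n
  sig_seq <- if (fps + fms > 0) (fps - fms)^2 / (fps + fms) else 0
  mean((sig - sig_seq)^2)
}

# candidate maximally segregated charge layouts: the three classes as
# contiguous blocks, in all six orders
kappa_segregated_layouts <- function(n_pos, n_neg, n_zero) {
  blocks <- list(POS = rep(1L, n_pos), NEG = rep(-1L, n_neg),
                 ZER = rep(0L, n_zero))
  orders <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(orders, function(o) unlist(blocks[o], use.names = FALSE))
}

#' Charge-patterning coefficient kappa (Das--Pappu)
#'
#' Blob-based charge-segregation statistic in `[0, 1]`: 0 for well-mixed
#' charges, 1 for a maximally blocky arrangement. Charge asymmetry is
#' evaluated over overlapping blobs of 5 and 6 residues; each blob-size
#' statistic is normalised by its value on the maximally segregated
#' arrangement of the identical composition (the maximum over the six
#' block-orderings of the positive, negative and zero-charge classes), and the
#' two normalised values are averaged. Aromatic and neutral beads carry zero
#' charge.
#'
#' @param seq a `cg_sequence` with at least one charged residue and length
#'   at least 6.
#' @return kappa, a dimensionless scalar in `[0, 1]` (0 when the composition
#'   admits only one blob profile, e.g. a charge homopolymer).
#' @examples
#' compute_kappa(coarse_sequence(c(rep("NEG", 10), rep("POS", 10))))
#' @export
compute_kappa <- function(seq) {
  stopifnot(inherits(seq, "cg_sequence"))
  q <- sequence_charges(seq)
  if (length(q) < 6L) stop("kappa undefined: sequence shorter than 6 residues")
  if (all(q == 0L)) stop("kappa undefined: sequence has no charged residues")
  kappa_of_charges(q)
}

# kappa on a raw charge vector; shared by compute_kappa and the designer
kappa_of_charges <- function(q) {
  layouts <- kappa_segregated_layouts(sum(q == 1L), sum(q == -1L),
                                      sum(q == 0L))
  ks <- vapply(c(5L, 6L), function(g) {
    d <- kappa_delta(q, g)
    # normalising delta: the most segregated of the canonical block layouts;
    # rare arrangements where neutral beads separate the charge blocks can
    # exceed it, so the sequence's own delta caps kappa at 1
    dmax <- max(vapply(layouts, kappa_delta, numeric(1), g = g), d)
    if (dmax <= .Machine$double.eps) 0 else d / dmax
  }, numeric(1))
  mean(ks)
}

#' Sequence charge decoration (SCD)
#'
#' Distance-weighted pairwise charge sum
#' `SCD = (1/N) * sum_{i<j} q_i q_j sqrt(j - i)`; aromatic and neutral beads
#' carry zero charge. Negative values indicate alternating charge patterns,
#' positive values blocky same-sign clustering.
#'
#' @param seq a `cg_sequence` of length at least 2.
#' @return signed dimensionless scalar.
#' @export
compute_scd <- function(seq) {
  stopifnot(inherits(seq, "cg_sequence"))
  n <- seq$length
  if (n < 2L) stop("SCD requires length >= 2")
  q <- sequence_charges(seq)
  idx <- which(q != 0L)
  if (length(idx) < 2L) return(0)
  qq <- outer(q[idx], q[idx])
  dd <- sqrt(abs(outer(idx, idx, "-")))
  sum(qq[upper.tri(qq)] * dd[upper.tri(dd)]) / n
}

#' All patterning metrics of a coarse sequence
#'
#' @param seq a `cg_sequence`.
#' @return one-row `data.frame` with id, length, fcr, phi, f_plus, f_minus,
#'   net_charge, kappa (NA where undefined) and scd.
#' @export
sequence_metrics <- function(seq) {
  fr <- compute_fractions(seq)
  kap <- tryCatch(compute_kappa(seq), error = function(e) NA_real_)
  scd <- if (seq$length >= 2L) compute_scd(seq) else NA_real_
  data.frame(id = seq$id, length = seq$length, fcr = fr$fcr, phi = fr$phi,
             f_plus = fr$f_plus, f_minus = fr$f_minus,
             net_charge = fr$net_charge, kappa = kap, scd = scd,
             stringsAsFactors = FALSE)
}

#' Specification for a kappa-targeted sequence design
#'
#' @param length total number of residues.
#' @param n_pos,n_neg,n_aro counts of positive, negative and aromatic beads;
#'   must sum to `length`.
#' @param kappa_target numeric target in `[0, 1]`, or `"minimize"` /
#'   `"maximize"`.
#' @param kappa_tolerance acceptable `|kappa - target|` for convergence
#'   (ignored for extremisation).
#' @param n_proposals number of Monte-Carlo swap proposals.
#' @param seed integer seed making the design deterministic.
#' @return a `cg_design_spec` list.
#' @export
design_spec <- function(length, n_pos, n_neg, n_aro,
                        kappa_target = "minimize", kappa_tolerance = 0.02,
                        n_proposals = 10000L, seed = 1L) {
  stopifnot(length >= 1, n_pos >= 0, n_neg >= 0, n_aro >= 0,
            n_proposals >= 1)
  if (n_pos + n_neg + n_aro != length) {
    stop("infeasible composition: counts sum to ", n_pos + n_neg + n_aro,
         ", not ", length)
  }
  if (is.character(kappa_target)) {
    kappa_target <- match.arg(kappa_target, c("minimize", "maximize"))
  } else {
    stopifnot(is.numeric(kappa_target), kappa_target >= 0, kappa_target <= 1)
  }
  structure(list(length = as.integer(length), n_pos = as.integer(n_pos),
                 n_neg = as.integer(n_neg), n_aro = as.integer(n_aro),
                 kappa_target = kappa_target,
                 kappa_tolerance = kappa_tolerance,
                 n_proposals = as.integer(n_proposals),
                 seed = as.integer(seed)),
            class = "cg_design_spec")
}

#' Design a sequence by kappa-targeted stochastic shuffling
#'
#' Starting from a random shuffle of the requested composition, proposes
#' swaps of two unequal residues and accepts a proposal greedily whenever it
#' does not worsen the objective (`|kappa - target|`, or `kappa` itself for
#' extremisation; equal-objective proposals are accepted, giving seeded
#' tie-breaking). The composition is preserved exactly throughout.
#'
#' @param spec a `cg_design_spec`.
#' @return list of class `cg_design` with elements `sequence`
#'   (a `cg_sequence`), `kappa` (achieved), `metrics` (via
#'   [sequence_metrics()]), `converged` (logical; always `TRUE` for
#'   extremisation), and `n_accepted`.
#' @examples
#' d <- design_spec(20, 8, 8, 4, kappa_target = "minimize",
#'                  n_proposals = 500, seed = 7)
#' design_sequence(d)$kappa
#' @export
design_sequence <- function(spec) {
  stopifnot(inherits(spec, "cg_design_spec"))
  if (spec$n_pos + spec$n_neg == 0L) {
    stop("kappa-targeted design needs at least one charged residue")
  }
  if (spec$length < 6L) stop("kappa-targeted design needs length >= 6")
  set.seed(spec$seed)
  res <- sample(c(rep("POS", spec$n_pos), rep("NEG", spec$n_neg),
                  rep("ARO", spec$n_aro)))
  q <- integer(spec$length)
  q[res == "POS"] <- 1L; q[res == "NEG"] <- -1L

  objective <- switch(as.character(spec$kappa_target[1]),
    minimize = function(k) k,
    maximize = function(k) -k,
    function(k) abs(k - spec$kappa_target))
  kap <- kappa_of_charges(q)
  obj <- objective(kap)
  n_acc <- 0L
  for (p in seq_len(spec$n_proposals)) {
    ij <- sample.int(spec$length, 2L)
    if (res[ij[1]] == res[ij[2]]) next
    res2 <- res; res2[ij] <- res[rev(ij)]
    q2 <- q; q2[ij] <- q[rev(ij)]
    kap2 <- kappa_of_charges(q2)
    if (objective(kap2) <= obj) {
      res <- res2; q <- q2; kap <- kap2; obj <- objective(kap2)
      n_acc <- n_acc + 1L
    }
    if (is.numeric(spec$kappa_target) &&
        abs(kap - spec$kappa_target) <= spec$kappa_tolerance) break
  }
  converged <- if (is.numeric(spec$kappa_target)) {
    abs(kap - spec$kappa_target) <= spec$kappa_tolerance
  } else TRUE
  seq <- coarse_sequence(res, id = sprintf("design_k%.3f", kap))
  structure(list(sequence = seq, kappa = kap, metrics = sequence_metrics(seq),
                 converged = converged, n_accepted = n_acc, spec = spec),
            class = "cg_design")
}

#' @export
print.cg_design <- function(x, ...) {
  cat("<cg_design> target:", as.character(x$spec$kappa_target),
      " achieved kappa:", format(x$kappa, digits = 4),
      if (!x$converged) " (UNCONVERGED)" else "", "\n")
  print(x$sequence)
  invisible(x)
}

#' Replace charged residue pairs by aromatic residues
#'
#' Converts `n_pairs` positive and `n_pairs` negative residues (chosen by a
#' seeded random draw) to aromatic beads, preserving the sequence net charge
#' and length. This is the move that generates an aromatic-enriched series
#' from a charge-rich parent sequence.
#'
#' @param seq a `cg_sequence` with at least `n_pairs` POS and `n_pairs` NEG
#'   residues.
#' @param n_pairs number of (+,-) pairs to convert.
#' @param seed integer seed.
#' @return a new `cg_sequence`.
#' @export
mutate_charged_to_aromatic <- function(seq, n_pairs, seed = 1L) {
  stopifnot(inherits(seq, "cg_sequence"), n_pairs >= 0)
  if (n_pairs == 0L) return(seq)
  ip <- which(seq$residues == "POS")
  im <- which(seq$residues == "NEG")
  if (length(ip) < n_pairs || length(im) < n_pairs) {
    stop("insufficient charged residues: need ", n_pairs,
         " of each sign, have ", length(ip), " POS and ", length(im), " NEG")
  }
  set.seed(seed)
  res <- seq$residues
  res[sample(ip, n_pairs)] <- "ARO"
  res[sample(im, n_pairs)] <- "ARO"
  coarse_sequence(res, id = paste0(seq$id, "_aro+", n_pairs))
}

#' Read sequences from a FASTA file
#'
#' @param path FASTA file. With `alphabet = "aa"` records are classified via
#'   [classify_sequence()]; with `"coarse"` the one-letter coarse encoding
#'   (K = positive, E = negative, F = aromatic, G = neutral) is decoded
#'   directly.
#' @param alphabet `"aa"` or `"coarse"`.
#' @return list of `cg_sequence` objects.
#' @export
read_fasta_sequences <- function(path, alphabet = c("aa", "coarse")) {
  alphabet <- match.arg(alphabet)
  set <- Biostrings::readAAStringSet(path)
  out <- vector("list", length(set))
  for (i in seq_along(set)) {
    s <- as.character(set[[i]])
    id <- names(set)[i]
    out[[i]] <- if (alphabet == "aa") classify_sequence(s, id = id)
                else coarse_sequence(s, id = id)
  }
  out
}

#' Write coarse sequences to a FASTA file (coarse one-letter encoding)
#'
#' @param seqs list of `cg_sequence` objects.
#' @param path output path.
#' @export
write_fasta_sequences <- function(seqs, path) {
  if (inherits(seqs, "cg_sequence")) seqs <- list(seqs)
  strs <- vapply(seqs, as.character, character(1))
  ids <- vapply(seqs, function(s) s$id, character(1))
  set <- Biostrings::AAStringSet(strs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Write a metrics table (one row per sequence) to CSV
#'
#' @param seqs list of `cg_sequence` objects.
#' @param path output CSV path.
#' @return the metrics `data.frame`, invisibly.
#' @export
write_sequence_metrics <- function(seqs, path) {
  if (inherits(seqs, "cg_sequence")) seqs <- list(seqs)
  tab <- do.call(rbind, lapply(seqs, sequence_metrics))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Design the aromatic-content series of model peptides
#'
#' Builds the net-neutral 40-mer series used throughout the package: S1 has
#' 18 positive, 18 negative and 4 aromatic residues (phi = 0.1, FCR = 0.9);
#' S2, S3 and S4 share the composition 14/14/12 (phi = 0.3) and differ only
#' in charge patterning; S5 has 8/8/24 (phi = 0.6, FCR = 0.4). Default kappa
#' targets are 0.47 (S1), 0.36 (S2), 0.20 (S3, a mid value: only the S2-S4
#' span 0.36-0.03 is pinned for the middle of the series), 0.03 (S4) and
#' 0.21 (S5).
#'
#' @param kappa_targets numeric vector of length 5, kappa target per design.
#' @param seed integer seed.
#' @param n_proposals proposals per design.
#' @return named list of `cg_design` objects (`S1` ... `S5`).
#' @export
design_series <- function(kappa_targets = c(0.47, 0.36, 0.20, 0.03, 0.21),
                          seed = 1L, n_proposals = 10000L) {
  n_aro <- c(4L, 12L, 12L, 12L, 24L)
  out <- vector("list", 5L)
  for (i in 1:5) {
    n_ch <- (40L - n_aro[i]) %/% 2L
    sp <- design_spec(40L, n_ch, n_ch, n_aro[i],
                      kappa_target = kappa_targets[i],
                      n_proposals = n_proposals, seed = seed + i)
    out[[i]] <- design_sequence(sp)
    out[[i]]$sequence$id <- paste0("S", i)
  }
  names(out) <- paste0("S", 1:5)
  out
}
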