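# Standard genetic code (codon -> one-letter amino acid, '*' = stop).
.GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Relative adaptiveness weights from a codon-usage table
#'
#' Standard construction: within each synonymous family, a codon's weight is
#' its usage frequency divided by the family's maximum, so every amino
#' acid's optimal codon has weight 1 and all weights lie in (0, 1]. Stop
#' codons are excluded. Codons with zero counts receive a small floor
#' (half the smallest nonzero family frequency) so geometric means stay
#' defined.
#'
#' @param usage Data frame with columns `codon` and `count` (or `freq`), or
#'   a named numeric vector of counts keyed by codon.
#' @return Named numeric vector of weights for the 61 sense codons.
#' @export
cai_weights <- function(usage) {
  if (is.data.frame(usage)) {
    if (!"codon" %in% names(usage)) stop("'usage' needs a 'codon' column")
    cnt_col <- intersect(c("count", "freq", "weight"), names(usage))[1]
    if (is.na(cnt_col)) stop("'usage' needs a 'count' or 'freq' column")
    counts <- stats::setNames(as.numeric(usage[[cnt_col]]), toupper(usage$codon))
  } else if (is.numeric(usage) && !is.null(names(usage))) {
    counts <- stats::setNames(as.numeric(usage), toupper(names(usage)))
  } else stop("'usage' must be a data frame or named numeric vector")
  sense <- names(.GENETIC_CODE)[.GENETIC_CODE != "*"]
  missing <- setdiff(sense, names(counts))
  if (length(missing)) stop(sprintf("usage table missing codon(s): %s",
                                    paste(utils::head(missing, 5), collapse = ", ")))
  if (any(counts < 0)) stop("usage counts must be non-negative")
  counts <- counts[sense]
  aa <- .GENETIC_CODE[sense]
  w <- unlist(lapply(split(counts, aa), function(fam) {
    mx <- max(fam)
    if (mx == 0) stop("an amino acid family has all-zero usage")
    fam / mx
  }), use.names = TRUE)
  # split() prefixes names with the amino acid; restore codon names
  names(w) <- sub("^.*\\.", "", names(w))
  w <- w[sense]
  nz <- w[w > 0]
  w[w == 0] <- min(nz) / 2
  w
}

#' Positional codon adaptation index profile
#'
#' For each coding sequence, the positional CAI at codon i is the geometric
#' mean of the relative-adaptiveness weights over a window of codons
#' centered at i (truncated at the sequence ends). The profile is the
#' arithmetic mean of the per-sequence values over all sequences long enough
#' to cover each position -- the standard view for visualizing the 5'
#' translational ramp.
#'
#' @param seqs Character vector (or list) of coding sequences (A/C/G/T,
#'   length divisible by 3). A single terminal stop codon is dropped;
#'   internal codons must all have a weight.
#' @param weights Named numeric weight vector as from [cai_weights()], all
#'   in (0, 1].
#' @param window Window width in codons (>= 1; default 21).
#' @param positions Codon positions to profile (default: 1 through the
#'   longest sequence).
#' @return Data frame with columns `position`, `mean_cai`, `n_seqs`.
#' @export
cai_profile <- function(seqs, weights, window = 21, positions = NULL) {
  if (is.list(seqs)) seqs <- vapply(seqs, paste0, character(1), collapse = "")
  stopifnot(is.character(seqs), length(seqs) >= 1L)
  if (!is.numeric(weights) || is.null(names(weights)))
    stop("'weights' must be a named numeric vector")
  if (any(weights <= 0 | weights > 1)) stop("weights must lie in (0, 1]")
  if (!is.numeric(window) || window < 1 || window != round(window))
    stop("'window' must be an integer >= 1")
  names(weights) <- toupper(names(weights))
  per_seq <- lapply(seqs, function(s) {
    s <- toupper(gsub("\\s", "", s))
    if (nchar(s) %% 3 != 0) stop("sequence length must be divisible by 3")
    codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    if (length(codons) > 1L && .GENETIC_CODE[codons[length(codons)]] %in% "*")
      codons <- codons[-length(codons)]
    unknown <- setdiff(codons, names(weights))
    if (length(unknown)) stop(sprintf("no weight for codon(s): %s",
                                      paste(unique(unknown), collapse = ", ")))
    log(weights[codons])
  })
  half_lo <- floor((window - 1) / 2)
  half_hi <- floor(window / 2)
  if (is.null(positions)) positions <- seq_len(max(lengths(per_seq)))
  prof <- vapply(positions, function(p) {
    vals <- unlist(lapply(per_seq, function(lw) {
      n <- length(lw)
      if (p > n) return(NULL)
      idx <- max(1L, p - half_lo):min(n, p + half_hi)
      exp(mean(lw[idx]))
    }))
    if (is.null(vals)) c(NA_real_, 0) else c(mean(vals), length(vals))
  }, numeric(2))
  data.frame(position = positions, mean_cai = prof[1, ], n_seqs = as.integer(prof[2, ]))
}

#' Read coding sequences from a FASTA file
#'
#' @param path Path to an uncompressed FASTA file of nucleotide sequences.
#' @return Named character vector of uppercase sequences.
#' @export
read_coding_sequences <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  fa <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE)
  stats::setNames(toupper(vapply(fa, `[[`, character(1), 1)), names(fa))
}
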