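BASES <- c("A", "C", "G", "T")

# Sum a vector so that the result is bit-identical for the reversed vector:
# pair symmetric elements first (addition of two doubles is commutative),
# then accumulate the pair sums. Used so the strand-symmetry invariant of
# the average odds score holds exactly in floating point.
palindromic_sum <- function(x) {
  n <- length(x)
  if (n == 0L) return(0)
  h <- n %/% 2L
  s <- if (h > 0L) sum(x[seq_len(h)] + x[n + 1L - seq_len(h)]) else 0
  if (n %% 2L == 1L) s <- s + x[h + 1L]
  s
}

# rows of a matrix summed with the palindromic pairing over columns
palindromic_rowsums <- function(m) {
  w <- ncol(m)
  h <- w %/% 2L
  s <- rep(0, nrow(m))
  for (j in seq_len(h)) s <- s + (m[, j] + m[, w + 1L - j])
  if (w %% 2L == 1L) s <- s + m[, h + 1L]
  s
}

revcomp_pwm <- function(pwm) {
  pwm[rev(seq_len(nrow(pwm))), c(4L, 3L, 2L, 1L), drop = FALSE]
}

#' Average odds score of a sequence under a PWM
#'
#' Every window of PWM width, on both strands, is scored by its odds: the
#' product over positions of `pwm[j, base] / background[base]`. The score is
#' the arithmetic mean over all scored windows. Windows containing a
#' non-ACGT character are skipped; a uniform PWM on the uniform background
#' scores exactly 1. Zero PWM probabilities are floored at `zero_floor`
#' (default 1e-4) before forming odds to avoid degenerate log-odds; set
#' `zero_floor = 0` to score exact zeros.
#'
#' The implementation accumulates both the within-window log-odds and the
#' across-window mean with a palindromic pairing, so
#' `average_odds_score(seq) == average_odds_score(revcomp(seq))` holds
#' bit-exactly.
#'
#' @param sequence A character string over A/C/G/T (case-insensitive; other
#'   letters invalidate the windows containing them).
#' @param pwm A `width x 4` probability matrix (columns A, C, G, T).
#' @param background Base frequencies, default uniform 0.25.
#' @param zero_floor Floor applied to PWM entries (default 1e-4).
#' @return The average odds score (>= 0), or `NA` if no window is scoreable.
#' @export
average_odds_score <- function(sequence, pwm, background = rep(0.25, 4),
                               zero_floor = 1e-4) {
  validate_pwm(pwm)
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 positive frequencies")
  }
  w <- nrow(pwm)
  if (w < 1L) stop("empty PWM")
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < w) stop("sequence shorter than PWM width")
  code <- match(strsplit(s, "")[[1L]], BASES)  # NA for non-ACGT

  if (zero_floor > 0) pwm <- pmax(pwm, zero_floor)
  lodds_f <- log(sweep(pwm, 2L, background, "/"))        # w x 4
  lodds_r <- log(sweep(revcomp_pwm(pwm), 2L, background, "/"))

  m <- L - w + 1L
  window_logs <- function(lo) {
    mat <- matrix(NA_real_, m, w)
    for (j in seq_len(w)) {
      b <- code[j:(j + m - 1L)]
      col <- lo[j, ][b]          # NA where base invalid
      mat[, j] <- col
    }
    mat
  }
  lf <- window_logs(lodds_f)
  lr <- window_logs(lodds_r)
  valid <- rowSums(is.na(lf)) == 0L  # same windows invalid on both strands
  if (!any(valid)) return(NA_real_)
  odds_f <- exp(palindromic_rowsums(lf[valid, , drop = FALSE]))
  odds_r <- exp(palindromic_rowsums(lr[valid, , drop = FALSE]))
  v <- odds_f + odds_r  # per-offset two-strand sum (commutative)
  palindromic_sum(v) / (2 * length(v))
}

#' Score many sequences against many PWMs
#'
#' @param sequences Named character vector (or `Biostrings::DNAStringSet`)
#'   of sequences.
#' @param pwms Named list of PWMs.
#' @inheritParams average_odds_score
#' @return data.frame `sequence_id`, `motif_id`, `score`. Sequences with no
#'   scoreable window are dropped with a counted warning.
#' @export
score_sequences <- function(sequences, pwms, background = rep(0.25, 4),
                            zero_floor = 1e-4) {
  if (methods::is(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  out <- list()
  n_dropped <- 0L
  for (sid in names(sequences)) {
    scores <- vapply(pwms, function(p) {
      average_odds_score(sequences[[sid]], p, background, zero_floor)
    }, numeric(1))
    if (anyNA(scores)) {
      n_dropped <- n_dropped + 1L
      next
    }
    out[[sid]] <- data.frame(sequence_id = sid, motif_id = names(pwms),
                             score = unname(scores),
                             stringsAsFactors = FALSE)
  }
  if (n_dropped > 0L) {
    warning(n_dropped, " sequence(s) with no scoreable window dropped")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Motif enrichment of positive sequences over matched controls
#'
#' Per motif, all positive (e.g. cLMR) and control sequences are scored by
#' the average odds score; the threshold is set from the control score
#' distribution (default: its 95th percentile) and a one-sided Fisher's
#' exact test asks whether positives exceed the threshold more often than
#' controls.
#'
#' @param positive_seqs,control_seqs Named character vectors or
#'   `DNAStringSet`s.
#' @param pwms Named list of PWMs.
#' @param threshold_policy `"ctrl-q95"` (default): 95th percentile of the
#'   control scores.
#' @param cell_type Optional label carried into the result.
#' @inheritParams average_odds_score
#' @return data.frame `motif_id`, `cell_type`, `threshold`, `pos_above`,
#'   `pos_below`, `ctrl_above`, `ctrl_below`, `p`, `degenerate`.
#' @export
motif_enrichment_test <- function(positive_seqs, control_seqs, pwms,
                                  threshold_policy = "ctrl-q95",
                                  cell_type = NA_character_,
                                  background = rep(0.25, 4),
                                  zero_floor = 1e-4) {
  if (!length(control_seqs)) stop("at least one control sequence required")
  if (!identical(threshold_policy, "ctrl-q95")) {
    stop("unknown threshold_policy: ", threshold_policy)
  }
  pos <- score_sequences(positive_seqs, pwms, background, zero_floor)
  ctl <- score_sequences(control_seqs, pwms, background, zero_floor)
  out <- do.call(rbind, lapply(names(pwms), function(mid) {
    ps <- pos$score[pos$motif_id == mid]
    cs <- ctl$score[ctl$motif_id == mid]
    thr <- stats::quantile(cs, 0.95, names = FALSE)
    a <- sum(ps > thr); b <- sum(ps <= thr)
    c_ <- sum(cs > thr); d <- sum(cs <= thr)
    degenerate <- length(unique(c(ps, cs))) == 1L
    p <- if (degenerate) 1 else
      stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE),
                         alternative = "greater")$p.value
    data.frame(motif_id = mid, cell_type = cell_type, threshold = thr,
               pos_above = a, pos_below = b, ctrl_above = c_,
               ctrl_below = d, p = p, degenerate = degenerate,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Motif-by-cell matrix of -log10 enrichment p-values
#'
#' @param results List (or row-bound data.frame) of
#'   [motif_enrichment_test()] outputs with `cell_type` filled in.
#' @param normalize `"none"` (default) or `"row_max"`: divide each motif row
#'   by its maximum.
#' @return Numeric matrix, motifs x cell types, rows/columns ordered by id;
#'   missing (motif, cell) combinations are `NA`.
#' @export
enrichment_matrix <- function(results, normalize = c("none", "row_max")) {
  normalize <- match.arg(normalize)
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  motifs <- sort(unique(results$motif_id))
  cells <- sort(unique(results$cell_type))
  m <- matrix(NA_real_, length(motifs), length(cells),
              dimnames = list(motifs, cells))
  m[cbind(match(results$motif_id, motifs),
          match(results$cell_type, cells))] <- -log10(results$p)
  if (normalize == "row_max") {
    mx <- apply(m, 1L, max, na.rm = TRUE)
    m <- m / ifelse(mx > 0, mx, 1)
  }
  m
}
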