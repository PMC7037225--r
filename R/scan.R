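# MATCH-style PWM scoring: per-position information weights, matrix and
# core similarity scores in [0,1].

# internal: score model for a pwm — weight matrix and min/max bounds
pwm_score_model <- function(p) {
  f <- pwm_freq(p)                       # L x 4, rows sum to 1
  info <- rowSums(f * log(4 * f))        # I(i) = sum_b f ln(4 f); >= 0
  w <- f * info                          # contribution of base b at pos i
  L <- nrow(f)
  core_len <- min(p$core_length, L)
  # core = contiguous block of core_len positions with maximal total info;
  # ties broken leftmost
  block <- vapply(seq_len(L - core_len + 1L),
                  function(s) sum(info[s:(s + core_len - 1L)]), numeric(1))
  cs <- which.max(block)
  core <- cs:(cs + core_len - 1L)
  list(w = w, info = info,
       min = apply(w, 1L, min), max = apply(w, 1L, max),
       core = core)
}

#' Matrix and core similarity of one window against a PWM
#'
#' The matrix similarity score is `(raw - Min) / (Max - Min)` where
#' `raw = sum_i I(i) f(i, b_i)`, `I(i) = sum_b f(i,b) ln(4 f(i,b))`, and
#' Min/Max are the per-position minimized/maximized raw scores. The core
#' similarity score is the same quantity restricted to the most
#' informative contiguous block of `core_length` positions. A degenerate
#' matrix with Max = Min scores 1.
#'
#' @param pwm A `pwm`.
#' @param window DNA string of the matrix length over `{A,C,G,T}`;
#'   windows containing `N` yield `NA` (no hit).
#' @return Named numeric vector `c(mss =, css =)`.
#' @export
match_score <- function(pwm, window) {
  sm <- pwm_score_model(pwm)
  L <- nrow(pwm$counts)
  stopifnot(nchar(window) == L)
  code <- match(strsplit(toupper(window), "")[[1L]], c("A", "C", "G", "T"))
  if (anyNA(code)) return(c(mss = NA_real_, css = NA_real_))
  raw <- sum(sm$w[cbind(seq_len(L), code)])
  denom <- sum(sm$max) - sum(sm$min)
  mss <- if (denom <= 0) 1 else (raw - sum(sm$min)) / denom
  rawc <- sum(sm$w[cbind(sm$core, code[sm$core])])
  denc <- sum(sm$max[sm$core]) - sum(sm$min[sm$core])
  css <- if (denc <= 0) 1 else (rawc - sum(sm$min[sm$core])) / denc
  c(mss = mss, css = css)
}

# internal: integer-encode a DNA string; N (or anything else) -> 5
encode_dna <- function(s) {
  code <- match(strsplit(s, "")[[1L]], c("A", "C", "G", "T"))
  code[is.na(code)] <- 5L
  code
}

# internal: score every window start of an encoded sequence against a
# score model; returns numeric vector of raw scores (positions with N get
# -Inf). `w5` is w with a 5th column of -Inf for N.
scan_raw <- function(code, w5) {
  L <- nrow(w5)
  n <- length(code) - L + 1L
  if (n < 1L) return(numeric(0))
  acc <- numeric(n)
  for (i in seq_len(L))
    acc <- acc + w5[i, code[i:(i + n - 1L)]]
  acc
}

# reverse complement on integer codes (A<->T, C<->G, N fixed)
revcomp_code <- function(code) rev(c(4L, 3L, 2L, 1L, 5L)[code])

#' Scan promoter sequences with a PWM library
#'
#' Every window position on both strands is scored; windows passing both
#' the matrix (`mss`) and core (`css`) similarity cutoffs are reported.
#' Reverse-strand hits are reported by the 0-based start of the matched
#' window on the forward strand. Overlapping hits are all kept.
#'
#' @param promoters A `promoter_set`.
#' @param pwms List of `pwm` objects.
#' @param mss_cutoff,css_cutoff Similarity cutoffs in `[0,1]`
#'   (defaults 0.85 and 0.90).
#' @return A `tfbs_hits` data.frame with columns `gene_id`, `pwm`,
#'   `start`, `end` (0-based, half-open), `strand`, `mss`, `css`, sorted
#'   by (gene, pwm, start, strand).
#' @export
scan_promoters <- function(promoters, pwms, mss_cutoff = 0.85,
                           css_cutoff = 0.90) {
  stopifnot(mss_cutoff >= 0, mss_cutoff <= 1,
            css_cutoff >= 0, css_cutoff <= 1)
  if (is.null(names(pwms)))
    names(pwms) <- vapply(pwms, `[[`, character(1), "name")
  codes <- lapply(promoters$sequence, encode_dna)
  out <- vector("list", length(pwms) * nrow(promoters) * 2L)
  k <- 0L
  for (pname in names(pwms)) {
    p <- pwms[[pname]]
    sm <- pwm_score_model(p)
    L <- nrow(p$counts)
    w5 <- cbind(sm$w, -Inf)
    den <- sum(sm$max) - sum(sm$min)
    core5 <- cbind(sm$w[sm$core, , drop = FALSE], -Inf)
    denc <- sum(sm$max[sm$core]) - sum(sm$min[sm$core])
    too_long <- nchar(promoters$sequence) < L
    if (any(too_long))
      warning("pwm '", pname, "' longer than ", sum(too_long),
              " promoter(s); skipped there", call. = FALSE)
    score_one <- function(code) {
      raw <- scan_raw(code, w5)
      mss <- if (den <= 0) ifelse(is.finite(raw), 1, -Inf)
             else (raw - sum(sm$min)) / den
      # core positions within the window start at offset core[1]-1
      rawc_full <- scan_raw(code, core5)
      idx <- seq_along(raw) + sm$core[[1L]] - 1L
      rawc <- rawc_full[idx]
      css <- if (denc <= 0) ifelse(is.finite(rawc), 1, -Inf)
             else (rawc - sum(sm$min[sm$core])) / denc
      list(mss = mss, css = css)
    }
    for (g in seq_len(nrow(promoters))) {
      code <- codes[[g]]
      if (length(code) < L) next
      fw <- score_one(code)
      pass <- which(fw$mss >= mss_cutoff & fw$css >= css_cutoff)
      if (length(pass) > 0L) {
        k <- k + 1L
        out[[k]] <- data.frame(gene_id = promoters$gene_id[[g]],
                               pwm = pname, start = pass - 1L,
                               strand = "+", mss = fw$mss[pass],
                               css = fw$css[pass],
                               stringsAsFactors = FALSE)
      }
      rc <- score_one(revcomp_code(code))
      pass <- which(rc$mss >= mss_cutoff & rc$css >= css_cutoff)
      if (length(pass) > 0L) {
        k <- k + 1L
        # position s' on the reverse complement maps to forward start
        # len - L - s' (0-based)
        out[[k]] <- data.frame(gene_id = promoters$gene_id[[g]],
                               pwm = pname,
                               start = length(code) - L - (pass - 1L),
                               strand = "-", mss = rc$mss[pass],
                               css = rc$css[pass],
                               stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (k == 0L)
    data.frame(gene_id = character(), pwm = character(),
               start = integer(), strand = character(),
               mss = numeric(), css = numeric(), stringsAsFactors = FALSE)
  else do.call(rbind, out[seq_len(k)])
  len_of <- setNames(vapply(pwms, function(p) nrow(p$counts), integer(1)),
                     names(pwms))
  hits$end <- hits$start + unname(len_of[hits$pwm])
  hits <- hits[order(hits$gene_id, hits$pwm, hits$start, hits$strand), ,
               drop = FALSE]
  rownames(hits) <- NULL
  hits <- hits[, c("gene_id", "pwm", "start", "end", "strand", "mss", "css")]
  class(hits) <- c("tfbs_hits", "data.frame")
  hits
}
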