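## Clinical evaluation statistics --------------------------------------------
##
## Data model and summaries for the reader-study tables shipped with the
## package: per-treatment five-point scores from two radiologists
## (registration quality is one score per treatment; position, clinical
## indication and confidence are per treated tumor) and the per-tumor
## residual-volume table. Transcribing the printed tables is data entry, not
## computation; the summaries here recompute every aggregate from the rows.

#' Path to a packaged clinical table
#'
#' @param which `"treatments"` (per-tumor volumes and residual percentages)
#'   or `"scores"` (five-point reader scores).
#' @return Path to the packaged CSV.
#' @export
ablafuse_table <- function(which = c("treatments", "scores")) {
  which <- match.arg(which)
  system.file("extdata", paste0(which, ".csv"), package = "ablafuse",
              mustWork = TRUE)
}

score_criteria <- c("reg_quality", "position", "clinical_indication",
                    "confidence")

#' Read a five-point score table
#'
#' Expects one row per treated tumor with columns
#' `<criterion>_r1` / `<criterion>_r2` for the criteria
#' `reg_quality`, `position`, `clinical_indication`, `confidence`
#' (values 1..5; registration quality may be NA on second-tumor rows of a
#' treatment, since one registration serves both).
#'
#' @param path CSV path; defaults to the packaged transcription.
#' @return A `data.frame` of class `score_table`.
#' @export
read_score_table <- function(path = ablafuse_table("scores")) {
  d <- read.csv(path)
  cols <- as.vector(outer(score_criteria, c("_r1", "_r2"), paste0))
  miss <- setdiff(cols, names(d))
  if (length(miss)) stop("score table lacks columns: ",
                         paste(miss, collapse = ", "))
  for (cl in cols) {
    v <- d[[cl]]
    if (!all(is.na(v) | (v %in% 1:5)))
      stop("scores must be integers in 1..5 (column ", cl, ")")
  }
  class(d) <- c("score_table", "data.frame")
  d
}

#' Read a residual-volume table
#'
#' One row per treated tumor: `tumor_volume_cm3`, `ablation_volume_cm3`,
#' `residual_volume_cm3`, `residual_percentage` (0..100).
#'
#' @param path CSV path; defaults to the packaged transcription.
#' @return A `data.frame` of class `residual_table`.
#' @export
read_residual_table <- function(path = ablafuse_table("treatments")) {
  d <- read.csv(path)
  need <- c("tumor_volume_cm3", "ablation_volume_cm3",
            "residual_volume_cm3", "residual_percentage")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("residual table lacks columns: ",
                         paste(miss, collapse = ", "))
  if (any(d$residual_percentage < 0 | d$residual_percentage > 100))
    stop("residual percentage outside [0, 100]")
  if (any(d[need[1:3]] < 0)) stop("volumes must be >= 0")
  class(d) <- c("residual_table", "data.frame")
  d
}

#' Per-rater, per-criterion score summaries
#'
#' Arithmetic mean and sample SD (n - 1 denominator) of every score column,
#' NA rows excluded; reported to 1 decimal alongside the raw values.
#'
#' @param t A [read_score_table()] result (non-empty).
#' @return Data frame: `criterion`, `rater`, `n`, `mean`, `sd` (raw) and
#'   `mean_1dp`, `sd_1dp` (rounded for reporting).
#' @export
summarize_scores <- function(t = read_score_table()) {
  if (nrow(t) == 0) stop("empty score table")
  rows <- expand.grid(criterion = score_criteria, rater = c("r1", "r2"),
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
    v <- t[[paste0(rows$criterion[i], "_", rows$rater[i])]]
    v <- v[!is.na(v)]
    data.frame(criterion = rows$criterion[i], rater = rows$rater[i],
               n = length(v), mean = mean(v), sd = sd(v))
  }))
  res$mean_1dp <- round_half_away(res$mean, 1)
  res$sd_1dp <- round_half_away(res$sd, 1)
  res
}

#' Student's t comparison of two score samples
#'
#' Classic Student statistics: `unpaired_equal_var` uses the pooled-variance
#' two-sample form with `n_a + n_b - 2` degrees of freedom; `paired` the
#' one-sample form on differences. Two-sided p from the t distribution.
#'
#' @param a,b Numeric vectors (n >= 2; equal length for `paired`).
#' @param mode `"unpaired_equal_var"` or `"paired"`.
#' @return List: `t`, `p`, `df`. Zero pooled variance with unequal means
#'   gives the infinite-t sentinel (`t = +-Inf`, `p = 0`).
#' @export
students_t <- function(a, b, mode = c("unpaired_equal_var", "paired")) {
  mode <- match.arg(mode)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) stop("need n >= 2 per sample")
  if (mode == "paired") {
    if (length(a) != length(b)) stop("paired mode requires equal lengths")
    d <- a - b
    df <- length(d) - 1
    s <- sd(d)
    if (s == 0) {
      t <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else t <- mean(d) / (s / sqrt(length(d)))
  } else {
    na <- length(a); nb <- length(b)
    df <- na + nb - 2
    sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / df
    if (sp2 == 0) {
      t <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
    } else t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  }
  p <- if (is.infinite(t)) 0 else 2 * pt(-abs(t), df)
  list(t = t, p = p, df = df)
}

#' Residual-volume aggregates over a treatment table
#'
#' Partitions the treated tumors into zero-residual, partial
#' (0 < pct < 100) and missed (pct = 100); summarises the partial set; and
#' counts retreatment candidates (missed, or partial at or above
#' `retreat_threshold` percent).
#'
#' @param t A [read_residual_table()] result (non-empty).
#' @param retreat_threshold Residual percentage triggering retreatment.
#' @return List: `n_total`, `n_zero`, `n_partial`, `n_missed`,
#'   `partial_percentages`, `mean_pct`, `sd_pct`, `min_pct`, `max_pct`
#'   (NA with `partial_defined = FALSE` when there are no partial rows),
#'   `n_retreat`, and `fractions` (percent of total, 1 decimal).
#' @export
residual_aggregates <- function(t = read_residual_table(),
                                retreat_threshold = 20) {
  if (nrow(t) == 0) stop("empty residual table")
  pct <- t$residual_percentage
  zero <- pct == 0; missed <- pct == 100
  partial <- !zero & !missed
  pp <- pct[partial]
  n <- nrow(t)
  n_retreat <- sum(missed) + sum(pp >= retreat_threshold)
  frac <- function(k) round_half_away(100 * k / n, 1)
  list(n_total = n, n_zero = sum(zero), n_partial = sum(partial),
       n_missed = sum(missed),
       partial_percentages = pp,
       partial_defined = length(pp) > 0,
       mean_pct = if (length(pp)) mean(pp) else NA_real_,
       sd_pct = if (length(pp) > 1) sd(pp) else NA_real_,
       min_pct = if (length(pp)) min(pp) else NA_real_,
       max_pct = if (length(pp)) max(pp) else NA_real_,
       n_retreat = n_retreat,
       fractions = c(zero = frac(sum(zero)), partial = frac(sum(partial)),
                     missed = frac(sum(missed)), retreat = frac(n_retreat)))
}
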