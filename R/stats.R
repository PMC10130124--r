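#' Paired within-subject t test with Cohen's dz
#'
#' Computes the paired-samples t statistic for aligned per-participant value
#' pairs: with differences `d_i = a_i - b_i`, `t = mean(d) / (sd(d)/sqrt(n))`
#' using the sample standard deviation (n-1 denominator), a two-sided p value
#' on `n - 1` degrees of freedom, the 95% confidence interval of the mean
#' difference `mean(d) +/- t_{0.975, n-1} * sd(d)/sqrt(n)`, and the
#' within-subject effect size Cohen's dz. dz is reported as a magnitude,
#' `|mean(d)| / sd(d)`; direction is carried by `t` and the confidence
#' interval. The identity `|t| = dz * sqrt(n)` holds exactly.
#'
#' @param a,b Numeric vectors of equal length, aligned by participant, with
#'   `n >= 2` and no missing values.
#' @param label_a,label_b Names for the two conditions (used in output).
#' @param alpha Significance threshold recorded with the result (the
#'   confidence interval stays at the 95% level regardless).
#' @param conf_level Confidence level of the interval, default 0.95.
#' @return An object of class `paired_t` with fields `label_a`, `label_b`,
#'   `n`, `mean_a`, `mean_b`, `mean_diff`, `t`, `df`, `p`, `ci_low`,
#'   `ci_high`, `dz`, `alpha_applied`, `significant`. `tidy()` returns it as a
#'   one-row tibble.
#' @export
#' @examples
#' res <- paired_t(c(1, 2, 3), c(2, 4, 9))
#' tidy(res)
paired_t <- function(a, b, label_a = "a", label_b = "b", alpha = 0.05,
                     conf_level = 0.95) {
  if (length(a) != length(b)) abort("paired samples must have equal length")
  if (anyNA(a) || anyNA(b)) abort("paired samples must not contain missing values")
  n <- length(a)
  if (n < 2) abort("insufficient data: paired t test needs n >= 2")
  d <- a - b
  sd_d <- sd(d)
  if (sd_d == 0) abort("degenerate sample: paired differences have zero variance")
  mean_d <- mean(d)
  se <- sd_d / sqrt(n)
  tstat <- mean_d / se
  df <- n - 1
  p <- 2 * pt(-abs(tstat), df)
  tcrit <- qt(1 - (1 - conf_level) / 2, df)
  res <- list(
    label_a = label_a, label_b = label_b, n = n,
    mean_a = mean(a), mean_b = mean(b), mean_diff = mean_d,
    t = tstat, df = df, p = p,
    ci_low = mean_d - tcrit * se, ci_high = mean_d + tcrit * se,
    dz = abs(mean_d) / sd_d,
    alpha_applied = alpha, significant = p < alpha
  )
  class(res) <- "paired_t"
  res
}

#' @exportS3Method generics::tidy
tidy.paired_t <- function(x, ...) {
  tibble::tibble(
    label_a = x$label_a, label_b = x$label_b, n = x$n,
    mean_a = x$mean_a, mean_b = x$mean_b, mean_diff = x$mean_diff,
    t = x$t, df = x$df, p = x$p, ci_low = x$ci_low, ci_high = x$ci_high,
    dz = x$dz, alpha_applied = x$alpha_applied, significant = x$significant
  )
}

#' @exportS3Method generics::glance
glance.paired_t <- function(x, ...) tidy(x)

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t test: %s vs %s (n = %d)\n", x$label_a, x$label_b, x$n))
  cat(sprintf("  means %.2f vs %.2f; t(%d) = %.3f, p = %.4g\n",
              x$mean_a, x$mean_b, x$df, x$t, x$p))
  cat(sprintf("  95%% CI of difference [%.3f, %.3f]; Cohen's dz = %.3f\n",
              x$ci_low, x$ci_high, x$dz))
  cat(sprintf("  %ssignificant at alpha = %.4g\n",
              if (x$significant) "" else "not ", x$alpha_applied))
  invisible(x)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise significance level, in `(0, 1]`.
#' @param m Number of comparisons in the family, integer >= 1.
#' @return `alpha / m`.
#' @export
#' @examples
#' bonferroni(0.05, 8)  # 0.00625
bonferroni <- function(alpha, m) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha > 1) {
    abort("alpha must be a single probability in (0, 1]")
  }
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != floor(m)) {
    abort("m must be a single integer >= 1")
  }
  alpha / m
}

# Per-participant percentage of a side's records matching a zone predicate.
# Returns a named vector over the given participants; NA where the
# participant has no records for that side.
participant_zone_pct <- function(records, participants, zone_flag, side = NULL) {
  scope <- if (is.null(side)) rep(TRUE, nrow(records)) else records$side == side
  denom <- tapply(scope, records$participant_id, sum)
  num <- tapply(scope & zone_flag, records$participant_id, sum)
  denom <- denom[match(participants, names(denom))]
  num <- num[match(participants, names(num))]
  out <- ifelse(!is.na(denom) & denom > 0, 100 * num / denom, NA_real_)
  names(out) <- participants
  out
}

#' The paper-style battery of within-subject zone and hand comparisons
#'
#' Runs two families of paired comparisons on per-participant frame
#' percentages:
#'
#' * **zones** (tested at `alpha`): pooling both hands, lower vs upper
#'   vertical hemiscene, and ipsilateral vs contralateral horizontal
#'   hemiscene.
#' * **hands** (tested at `bonferroni(alpha, family_size)`): eight
#'   left-hand vs right-hand comparisons — the lower and upper hemiscenes,
#'   the contralateral and ipsilateral hemiscenes, and the contralateral
#'   upper, ipsilateral upper, contralateral lower and ipsilateral lower
#'   quadrants. For these, each hand's percentage is taken over that hand's
#'   own records (e.g. the left hand's ipsilateral upper quadrant is UL).
#'
#' A comparison is skipped with a warning when any participant lacks records
#' for one of its members (the paired design would otherwise silently drop
#' participants), when fewer than two participants are available, or when the
#' paired differences have zero variance.
#'
#' @param records Hand-record tibble from [explode_hands()].
#' @param alpha Family-wise significance level, default 0.05.
#' @param family_size Bonferroni divisor for the hands family, default 8.
#' @return A tibble with one row per completed comparison: `comparison`,
#'   `family`, `label_a`, `label_b`, `n`, `mean_a`, `mean_b`, `t`, `df`, `p`,
#'   `ci_low`, `ci_high`, `dz`, `alpha_applied`, `significant`. Skipped
#'   comparisons are listed in the `skipped` attribute.
#' @export
comparison_battery <- function(records, alpha = 0.05, family_size = 8) {
  participants <- sort(unique(records$participant_id))
  alpha_hands <- bonferroni(alpha, family_size)

  upper <- records$vertical == "upper"
  lower <- records$vertical == "lower"
  ipsi <- records$laterality == "ipsilateral"
  contra <- records$laterality == "contralateral"

  pct <- function(zone_flag, side = NULL) {
    participant_zone_pct(records, participants, zone_flag, side)
  }

  spec <- list(
    list(comparison = "lower vs upper hemiscene", family = "zones",
         label_a = "lower", label_b = "upper", alpha = alpha,
         a = pct(lower), b = pct(upper)),
    list(comparison = "ipsilateral vs contralateral hemiscene", family = "zones",
         label_a = "ipsilateral", label_b = "contralateral", alpha = alpha,
         a = pct(ipsi), b = pct(contra)),
    list(comparison = "lower hemiscene", zone = lower),
    list(comparison = "upper hemiscene", zone = upper),
    list(comparison = "contralateral hemiscene", zone = contra),
    list(comparison = "ipsilateral hemiscene", zone = ipsi),
    list(comparison = "contralateral upper quadrant", zone = contra & upper),
    list(comparison = "ipsilateral upper quadrant", zone = ipsi & upper),
    list(comparison = "contralateral lower quadrant", zone = contra & lower),
    list(comparison = "ipsilateral lower quadrant", zone = ipsi & lower)
  )
  spec <- lapply(spec, function(s) {
    if (!is.null(s$zone)) {
      s$family <- "hands"
      s$label_a <- "left hand"
      s$label_b <- "right hand"
      s$alpha <- alpha_hands
      s$a <- pct(s$zone, side = "left")
      s$b <- pct(s$zone, side = "right")
      s$zone <- NULL
    }
    s
  })

  rows <- list()
  skipped <- character()
  for (s in spec) {
    if (length(participants) < 2) {
      skipped <- c(skipped, paste0(s$comparison, ": fewer than 2 participants"))
      next
    }
    if (anyNA(s$a) || anyNA(s$b)) {
      miss <- participants[is.na(s$a) | is.na(s$b)]
      skipped <- c(skipped, paste0(
        s$comparison, ": participant(s) without records for one member (",
        paste(head(miss, 5), collapse = ", "), ")"))
      next
    }
    res <- tryCatch(
      paired_t(unname(s$a), unname(s$b), s$label_a, s$label_b, alpha = s$alpha),
      error = function(e) NULL
    )
    if (is.null(res)) {
      skipped <- c(skipped, paste0(s$comparison, ": degenerate paired sample"))
      next
    }
    rows[[length(rows) + 1]] <- tidy(res) |>
      dplyr::mutate(comparison = s$comparison, family = s$family,
                    .before = "label_a")
  }
  if (length(skipped) > 0) {
    warn(paste0("skipped comparison(s):\n  ", paste(skipped, collapse = "\n  ")))
  }
  out <- if (length(rows) > 0) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(comparison = character(), family = character(),
                   label_a = character(), label_b = character(), n = integer(),
                   mean_a = double(), mean_b = double(), mean_diff = double(),
                   t = double(), df = double(), p = double(),
                   ci_low = double(), ci_high = double(), dz = double(),
                   alpha_applied = double(), significant = logical())
  }
  attr(out, "skipped") <- skipped
  out
}
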