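# Parental origin of validated CNVs from trio profiles, and the
# maternal-transmission bias test.

#' Assign parental origin of a child CNV from trio profiles
#'
#' A parent transmits when their profile contains a call consistent with
#' the child variant (same consistency rule as database matching). Exactly
#' one positive parent gives that origin; both parents available and
#' negative gives de novo; a missing parent with no positive in the other
#' gives unknown; both parents positive is flagged ambiguous rather than
#' silently resolved.
#'
#' @param child_calls the child's true variant calls (a `cgh_calls` tibble).
#' @param parent_profiles profiles of the available parents.
#' @param design the probe design.
#' @param mother,father sample labels of the parents in `parent_profiles`,
#'   or `NA` when that parent is unavailable.
#' @param parent_calls optional precomputed calls on the parents.
#' @param threshold segmentation threshold for parent calls.
#' @return the child calls with added columns `origin` ("maternal",
#'   "paternal", "de_novo", "unknown" or "ambiguous"), `mother_positive`,
#'   `father_positive` (logicals, `NA` when unavailable).
#' @export
assign_origin <- function(child_calls, parent_profiles, design,
                          mother = NA, father = NA, parent_calls = NULL,
                          threshold = 6) {
  avail <- c(mother = !is.na(mother), father = !is.na(father))
  if (is.null(parent_calls) && any(avail)) {
    keep <- parent_profiles$sample_id %in% c(mother, father)
    parent_calls <- detect_aberrations(parent_profiles[keep, ],
                                       threshold = threshold)
  }
  parent_positive <- function(parent_id, call) {
    pc <- parent_calls[parent_calls$sample_id == parent_id, ]
    if (nrow(pc) == 0) return(FALSE)
    any(vapply(seq_len(nrow(pc)), function(j) {
      intervals_consistent(call, tibble(chrom = pc$chrom[j],
                                        start = pc$inner_start[j],
                                        end = pc$inner_end[j],
                                        type = pc$type[j]), design)
    }, logical(1)))
  }
  res <- purrr::map_dfr(seq_len(nrow(child_calls)), function(i) {
    call <- child_calls[i, ]
    m_pos <- if (avail["mother"]) parent_positive(mother, call) else NA
    f_pos <- if (avail["father"]) parent_positive(father, call) else NA
    origin <- dplyr::case_when(
      isTRUE(m_pos) && isTRUE(f_pos) ~ "ambiguous",
      isTRUE(m_pos) ~ "maternal",
      isTRUE(f_pos) ~ "paternal",
      isFALSE(m_pos) && isFALSE(f_pos) ~ "de_novo",
      TRUE ~ "unknown"
    )
    tibble(origin = origin, mother_positive = m_pos, father_positive = f_pos)
  })
  out <- dplyr::bind_cols(child_calls, res)
  class(out) <- unique(c("cgh_calls", class(out)))
  out
}

#' Exact two-sided Clopper-Pearson confidence interval for a proportion
#'
#' Obtained by inverting binomial tail probabilities; at the edges the
#' closed forms apply: `k = n` gives lower bound `(alpha/2)^(1/n)` and upper
#' bound 1, `k = 0` gives 0 and `1 - (alpha/2)^(1/n)`.
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (>= 1).
#' @param alpha two-sided significance level (default 0.05 for a 95% CI).
#' @return a one-row tibble: `lower`, `upper`.
#' @export
#' @examples
#' clopper_pearson(7, 7) # lower = 0.025^(1/7)
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (n < 1 || k < 0 || k > n) abort("need 0 <= k <= n and n >= 1")
  lower <- if (k == 0) 0 else qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else qbeta(1 - alpha / 2, k + 1, n - k)
  tibble(lower = lower, upper = upper)
}

#' Exact binomial test of maternal transmission bias
#'
#' One-sided exact binomial tail `P(X >= n_maternal | n_inherited, p)`
#' against a null transmission probability of 0.5, with a two-sided
#' Clopper-Pearson interval for the maternal proportion. A two-sided
#' p-value (doubling rule, capped at 1) is available via `sided = "two"`.
#'
#' @param n_maternal maternally transmitted CNVs.
#' @param n_inherited all inherited CNVs (>= 1).
#' @param p null transmission probability (default 0.5).
#' @param sided `"one"` (default) or `"two"`.
#' @param conf_level confidence level of the interval (default 0.95).
#' @return a `transmission_test` object: `n_maternal`, `n_inherited`,
#'   `estimate`, `p_value`, `ci_lower`, `ci_upper`, `sided`, `conf_level`.
#' @export
#' @examples
#' binomial_bias_test(7, 7) # p = 0.5^7, CI [0.59, 1]
binomial_bias_test <- function(n_maternal, n_inherited, p = 0.5,
                               sided = c("one", "two"), conf_level = 0.95) {
  sided <- match.arg(sided)
  if (n_inherited < 1) abort("test undefined for zero inherited CNVs")
  if (n_maternal > n_inherited) abort("n_maternal cannot exceed n_inherited")
  p_one <- stats::pbinom(n_maternal - 1, n_inherited, p, lower.tail = FALSE)
  p_value <- if (sided == "one") p_one else min(1, 2 * min(p_one,
    stats::pbinom(n_maternal, n_inherited, p)))
  ci <- clopper_pearson(n_maternal, n_inherited, alpha = 1 - conf_level)
  structure(list(n_maternal = n_maternal, n_inherited = n_inherited,
                 estimate = n_maternal / n_inherited, p_value = p_value,
                 ci_lower = ci$lower, ci_upper = ci$upper,
                 sided = sided, conf_level = conf_level),
            class = "transmission_test")
}

#' @export
print.transmission_test <- function(x, ...) {
  cat(sprintf(
    "Maternal transmission: %d of %d inherited CNVs (%.1f%%, %d%% CI %.1f-%.1f%%), %s-sided p = %.4f\n",
    x$n_maternal, x$n_inherited, 100 * x$estimate,
    round(100 * x$conf_level), 100 * x$ci_lower, 100 * x$ci_upper,
    x$sided, x$p_value))
  invisible(x)
}

#' @method tidy transmission_test
#' @export
tidy.transmission_test <- function(x, ...) {
  tibble(estimate = x$estimate, statistic = x$n_maternal,
         p.value = x$p_value, conf.low = x$ci_lower, conf.high = x$ci_upper)
}

#' @method glance transmission_test
#' @export
glance.transmission_test <- function(x, ...) {
  tibble(n_maternal = x$n_maternal, n_inherited = x$n_inherited,
         estimate = x$estimate, p.value = x$p_value,
         conf.low = x$ci_lower, conf.high = x$ci_upper,
         sided = x$sided, conf.level = x$conf_level)
}
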