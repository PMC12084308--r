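#' Run the semantic-priming experiment on a network
#'
#' Every prime (related and unrelated) of every usable pair is activated
#' with [activation_matrix()]; the matrix is normalized (columns then
#' rows, see [normalize_matrix()]); and the normalized final activation of
#' each target is read off under its related and its unrelated prime. A
#' pair is excluded — with a recorded reason — unless its target and both
#' primes are present in the network.
#'
#' @param g the (reduced) semantic network.
#' @param pairs a `data.frame` with columns `target`, `related_prime`,
#'   `unrelated_prime` and optionally `rt_related`, `rt_unrelated`
#'   (see [read_ldt_pairs()]).
#' @param params a [spread_params()].
#' @return a `data.frame` of class `priming_outcomes`, two rows per usable
#'   pair (`prime_type` `"related"` / `"unrelated"`) with columns `pair`,
#'   `target`, `prime`, `prime_type`, `activation`, `rt`; excluded pairs
#'   are in attribute `"exclusions"` (`target`, `reason`).
#' @export
run_priming <- function(g, pairs, params = spread_params()) {
  nodes <- igraph::V(g)$name
  present <- function(x) x %in% nodes
  reasons <- character(nrow(pairs))
  ok <- rep(TRUE, nrow(pairs))
  for (col in c("target", "related_prime", "unrelated_prime")) {
    miss <- !present(pairs[[col]])
    reasons[miss & ok] <- paste0(col, " '", pairs[[col]][miss & ok],
                                 "' not in network")
    ok <- ok & !miss
  }
  if (!any(ok)) stop("no usable prime-target pairs: every pair has a node ",
                     "absent from the network")
  used <- pairs[ok, , drop = FALSE]
  primes <- unique(c(used$related_prime, used$unrelated_prime))
  m <- activation_matrix(g, primes, params)
  mn <- normalize_matrix(m)

  n <- nrow(used)
  has_rt <- all(c("rt_related", "rt_unrelated") %in% names(used))
  out <- data.frame(
    pair = rep(seq_len(n), each = 2L),
    target = rep(used$target, each = 2L),
    prime = as.vector(rbind(used$related_prime, used$unrelated_prime)),
    prime_type = rep(c("related", "unrelated"), n),
    stringsAsFactors = FALSE
  )
  out$activation <- mn[cbind(match(out$target, rownames(mn)),
                             match(out$prime, colnames(mn)))]
  out$rt <- if (has_rt) {
    as.vector(rbind(used$rt_related, used$rt_unrelated))
  } else NA_real_
  attr(out, "exclusions") <- data.frame(
    target = pairs$target[!ok], reason = reasons[!ok],
    stringsAsFactors = FALSE)
  attr(out, "params") <- attr(m, "params")
  class(out) <- c("priming_outcomes", "data.frame")
  out
}

#' Paired Wilcoxon signed-rank test with rank-biserial effect size
#'
#' Two-sided Wilcoxon signed-rank test on paired samples. Zero differences
#' are dropped before ranking (classical treatment; the number dropped is
#' returned). The effect size is the matched-pairs rank biserial,
#' \eqn{(T^+ - T^-) / (T^+ + T^-)} on the signed ranks: +1 when every
#' difference is positive, -1 when every difference is negative, and it
#' flips sign exactly when `x` and `y` are swapped.
#'
#' @param x,y equal-length numeric vectors (paired observations). At least
#'   5 nonzero differences are required, unless all differences are zero
#'   (effect size 0, p = 1).
#' @return list: `statistic` (\eqn{T^+}), `p_value`, `effect_size`,
#'   `n_used` (nonzero differences), `n_zero_dropped`.
#' @export
wilcoxon_paired <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  d <- x - y
  d <- d[!is.na(d)]
  nonzero <- d[d != 0]
  if (length(nonzero) == 0) {
    return(list(statistic = 0, p_value = 1, effect_size = 0,
                n_used = 0L, n_zero_dropped = length(d)))
  }
  if (length(nonzero) < 5) {
    stop("need at least 5 nonzero paired differences; got ", length(nonzero))
  }
  r <- rank(abs(nonzero))
  t_pos <- sum(r[nonzero > 0])
  t_neg <- sum(r[nonzero < 0])
  es <- (t_pos - t_neg) / (t_pos + t_neg)
  p <- suppressWarnings(
    stats::wilcox.test(nonzero, alternative = "two.sided", mu = 0)$p.value
  )
  list(statistic = t_pos, p_value = p, effect_size = es,
       n_used = length(nonzero), n_zero_dropped = sum(d == 0))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks on ties (two-sided p-value).
#' Constant input is an error: the correlation is undefined.
#'
#' @param a,b equal-length numeric vectors, length >= 3.
#' @return list: `rho`, `p_value`, `n`.
#' @export
spearman_rho <- function(a, b) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 3) stop("need at least 3 complete observations")
  if (length(unique(a)) < 2 || length(unique(b)) < 2) {
    stop("Spearman correlation is undefined for constant input")
  }
  ct <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                         alternative = "two.sided"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(a))
}

#' Summarize a priming experiment
#'
#' Paired Wilcoxon test of the normalized target activations under related
#' vs unrelated primes (positive effect size = higher activation under the
#' related prime), plus the Spearman correlation between activation and
#' reaction time pooled over all included prime-target observations (a
#' negative rho means higher activation goes with faster responses).
#'
#' @param outcomes a `priming_outcomes` frame from [run_priming()].
#' @return list of class `priming_stats`: `n_pairs`, `n_excluded`,
#'   `statistic`, `p_value`, `effect_size`, `spearman_rho`, `rho_p_value`,
#'   `rho_n`, `n_zero_dropped`.
#' @export
priming_report <- function(outcomes) {
  rel <- outcomes[outcomes$prime_type == "related", ]
  unrel <- outcomes[outcomes$prime_type == "unrelated", ]
  rel <- rel[order(rel$pair), ]
  unrel <- unrel[order(unrel$pair), ]
  w <- wilcoxon_paired(rel$activation, unrel$activation)
  rho <- list(rho = NA_real_, p_value = NA_real_, n = 0L)
  if (any(is.finite(outcomes$rt))) {
    rho <- spearman_rho(outcomes$activation, outcomes$rt)
  }
  excl <- attr(outcomes, "exclusions")
  structure(list(
    n_pairs = nrow(rel),
    n_excluded = if (is.null(excl)) 0L else nrow(excl),
    statistic = w$statistic,
    p_value = w$p_value,
    effect_size = w$effect_size,
    spearman_rho = rho$rho,
    rho_p_value = rho$p_value,
    rho_n = rho$n,
    n_zero_dropped = w$n_zero_dropped
  ), class = "priming_stats")
}

#' @export
print.priming_stats <- function(x, ...) {
  cat(sprintf("Priming: %d pairs (%d excluded)\n", x$n_pairs, x$n_excluded))
  cat(sprintf("  Wilcoxon V = %.1f, p = %.3g, rank-biserial effect size = %.3f\n",
              x$statistic, x$p_value, x$effect_size))
  if (is.finite(x$spearman_rho)) {
    cat(sprintf("  Spearman rho(activation, RT) = %.3f (p = %.3g, n = %d)\n",
                x$spearman_rho, x$rho_p_value, x$rho_n))
  }
  invisible(x)
}

#' Probe implicit bias with priming asymmetries
#'
#' Runs the same spreading-activation machinery with stereotype probes:
#' each probe row pairs a target with a stereotype-consistent prime (e.g.
#' doctor–man, nurse–woman) and a stereotype-inconsistent one (doctor–woman,
#' nurse–man). The consistent prime plays the "related" role, so a positive
#' effect size means consistent primes activate their targets more than
#' inconsistent ones — larger effect sizes indicate greater stereotype
#' bias in the network. An optional `label` column splits the probes into
#' separately analyzed groups.
#'
#' @param g the semantic network.
#' @param probe_pairs `data.frame` with columns `target`,
#'   `consistent_prime`, `inconsistent_prime` and optionally `label`,
#'   `rt_consistent`, `rt_inconsistent`.
#' @param params a [spread_params()].
#' @return a `priming_stats` object, or a named list of them (one per
#'   label) when `label` is present.
#' @export
bias_probe <- function(g, probe_pairs, params = spread_params()) {
  need <- c("target", "consistent_prime", "inconsistent_prime")
  if (!all(need %in% names(probe_pairs))) {
    stop("probe_pairs must have columns: ", paste(need, collapse = ", "))
  }
  as_pairs <- function(df) {
    out <- data.frame(target = df$target,
                      related_prime = df$consistent_prime,
                      unrelated_prime = df$inconsistent_prime,
                      stringsAsFactors = FALSE)
    if (all(c("rt_consistent", "rt_inconsistent") %in% names(df))) {
      out$rt_related <- df$rt_consistent
      out$rt_unrelated <- df$rt_inconsistent
    }
    out
  }
  if ("label" %in% names(probe_pairs)) {
    groups <- split(probe_pairs, probe_pairs$label)
    return(lapply(groups, function(df) {
      priming_report(run_priming(g, as_pairs(df), params))
    }))
  }
  priming_report(run_priming(g, as_pairs(probe_pairs), params))
}

#' Boxplot of activation by prime type
#'
#' Mirrors the validation figures: normalized final activation of the
#' targets, related vs unrelated primes.
#'
#' @param outcomes a `priming_outcomes` frame.
#' @param ... passed to [graphics::boxplot()].
#' @return invisibly, the boxplot statistics.
#' @export
plot_priming <- function(outcomes, ...) {
  invisible(graphics::boxplot(
    activation ~ prime_type, data = outcomes,
    ylab = "normalized final activation of target",
    xlab = "prime type", ...))
}
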