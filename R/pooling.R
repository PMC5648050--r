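# Equal-weight linear opinion pooling: the panel prior is the weighted
# mixture of the individual bivariate normal priors, not a single normal.
# The community of priors comprises the pooled panel, role subgroups, and
# the most-sceptical / most-enthusiastic individual experts.

#' Linear opinion pool of sensitivity priors
#'
#' Combines per-expert bivariate normal priors into a finite mixture with
#' the given weights (equal weights by default), preserving component
#' order.
#'
#' @param priors Non-empty list of [sensitivity_prior()] objects.
#' @param weights Optional non-negative weights summing to 1 (tolerance
#'   1e-12); default `1/N` each.
#' @param label Pool label (e.g. `"all"`, `"doctors"`, an expert id).
#' @return An object of class `pooled_prior`.
#' @examples
#' p1 <- sensitivity_prior("a", -0.05, 0.1, -0.01, 0.04, 0)
#' p2 <- sensitivity_prior("b", 0.02, 0.08, 0.03, 0.05, 0.5)
#' linear_pool(list(p1, p2))
#' @export
linear_pool <- function(priors, weights = NULL, label = "all") {
  if (inherits(priors, "sensitivity_prior")) priors <- list(priors)
  if (!is.list(priors) || !length(priors) ||
      !all(vapply(priors, inherits, logical(1), "sensitivity_prior")))
    stopf("linear_pool: 'priors' must be a non-empty list of sensitivity_prior objects")
  n <- length(priors)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (length(weights) != n)
    stopf("linear_pool: %d weights for %d components", length(weights), n)
  if (any(weights < 0)) stopf("linear_pool: weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-12)
    stopf("linear_pool: weights sum to %.15g, not 1", sum(weights))
  structure(list(components = priors, weights = as.numeric(weights),
                 label = as.character(label)),
            class = "pooled_prior")
}

#' @export
print.pooled_prior <- function(x, ...) {
  mo <- pool_moments(x)
  cat(sprintf("Pooled prior '%s': mixture of %d bivariate normal component(s)\n",
              x$label, length(x$components)))
  cat(sprintf("  mixture mean: delta_O = %.4f, delta_E = %.4f\n",
              mo$mean["delta_O"], mo$mean["delta_E"]))
  cat(sprintf("  mixture sd:   delta_O = %.4f, delta_E = %.4f, corr = %.3f\n",
              sqrt(mo$cov[1, 1]), sqrt(mo$cov[2, 2]),
              if (mo$cov[1, 1] > 0 && mo$cov[2, 2] > 0)
                mo$cov[1, 2] / sqrt(mo$cov[1, 1] * mo$cov[2, 2]) else 0))
  invisible(x)
}

#' @export
length.pooled_prior <- function(x) length(x$components)

#' Mean vector and covariance matrix of a pooled prior
#'
#' Standard mixture moments: `mean = sum w_k mu_k`;
#' `cov = sum w_k (Sigma_k + mu_k mu_k') - mu mu'`.
#'
#' @param p A [pooled_prior()].
#' @return `list(mean = length-2 vector, cov = 2x2 matrix)` with
#'   `delta_O`, `delta_E` naming.
#' @export
pool_moments <- function(p) {
  if (!inherits(p, "pooled_prior")) stopf("pool_moments: 'p' must be a pooled_prior")
  mu <- c(delta_O = 0, delta_E = 0)
  second <- matrix(0, 2, 2)
  for (k in seq_along(p$components)) {
    comp <- p$components[[k]]
    mk <- c(comp$mean_O, comp$mean_E)
    mu <- mu + p$weights[k] * mk
    second <- second + p$weights[k] * (vcov(comp) + tcrossprod(mk))
  }
  cov <- second - tcrossprod(mu)
  # symmetrise against rounding so eigen() sees an exact symmetric matrix
  cov <- (cov + t(cov)) / 2
  dimnames(cov) <- list(c("delta_O", "delta_E"), c("delta_O", "delta_E"))
  list(mean = mu, cov = cov)
}

#' Sample from a pooled prior
#'
#' Draws component indicators from the pool weights, then (delta_O,
#' delta_E) from the selected bivariate normal.  Reproducible under a
#' fixed seed; the enclosing RNG stream is restored afterwards when `seed`
#' is given.
#'
#' @param p A [pooled_prior()].
#' @param n Number of draws, `>= 1`.
#' @param seed Optional integer seed.
#' @return `n x 2` matrix with columns `delta_O`, `delta_E`; component
#'   indices in attribute `"component"`.
#' @export
sample_pool <- function(p, n, seed = NULL) {
  if (!inherits(p, "pooled_prior")) stopf("sample_pool: 'p' must be a pooled_prior")
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stopf("sample_pool: 'n' must be >= 1")
  with_seed(seed, {
    k <- sample.int(length(p$components), n, replace = TRUE, prob = p$weights)
    z1 <- stats::rnorm(n)
    z2 <- stats::rnorm(n)
    mo <- vapply(p$components, `[[`, numeric(1), "mean_O")[k]
    me <- vapply(p$components, `[[`, numeric(1), "mean_E")[k]
    so <- vapply(p$components, `[[`, numeric(1), "sd_O")[k]
    se <- vapply(p$components, `[[`, numeric(1), "sd_E")[k]
    rho <- vapply(p$components, `[[`, numeric(1), "rho")[k]
    out <- cbind(delta_O = mo + so * z1,
                 delta_E = me + se * (rho * z1 + sqrt(1 - rho^2) * z2))
    attr(out, "component") <- k
    out
  })
}

#' Marginal mixture density of a pooled prior
#'
#' @param p A [pooled_prior()].
#' @param x Evaluation points (utility scale).
#' @param arm `"O"` (open repair) or `"E"` (eEVAR).
#' @return Density values at `x`.
#' @export
dpool_marginal <- function(p, x, arm = c("O", "E")) {
  arm <- match.arg(arm)
  m <- vapply(p$components, `[[`, numeric(1), paste0("mean_", arm))
  s <- vapply(p$components, `[[`, numeric(1), paste0("sd_", arm))
  if (any(s <= 0))
    stopf("dpool_marginal: component(s) with zero sd have no density")
  out <- numeric(length(x))
  for (k in seq_along(m)) {
    out <- out + p$weights[k] * stats::dnorm(x, m[k], s[k])
  }
  out
}

#' Identify the most sceptical / most enthusiastic expert
#'
#' Experts are ranked by the prior mean of the elicited eEVAR-minus-OPEN
#' non-responder difference, `mean_E - mean_O` (a shared anchor gap adds a
#' constant and cannot change the ranking).  The most sceptical expert
#' minimises it (belief that open-repair non-responders fare relatively
#' better); the most enthusiastic maximises it.
#'
#' @param priors List of [sensitivity_prior()] objects.
#' @param which `"sceptical"` or `"enthusiastic"`.
#' @return The selected expert's id.
#' @export
find_extreme_expert <- function(priors, which = c("sceptical", "enthusiastic")) {
  which <- match.arg(which)
  d <- vapply(priors, function(p) p$mean_E - p$mean_O, numeric(1))
  idx <- if (which == "sceptical") which.min(d) else which.max(d)
  priors[[idx]]$expert_id
}

#' Select a community-of-priors member
#'
#' Returns the equal-weight pool over a role subgroup (`"all"`,
#' `"doctors"`, `"nurses"`), the single-expert pool for an explicit
#' `expert_id`, or the extreme individual priors (`"sceptic"`,
#' `"enthusiast"`, ranked by [find_extreme_expert()]).
#'
#' @param set The [elicitation_set()] supplying role metadata.
#' @param priors List of [sensitivity_prior()] objects (typically from
#'   [build_panel_priors()]; may be a filtered subset of the set).
#' @param group `"all"`, `"doctors"`, `"nurses"`, `"sceptic"`,
#'   `"enthusiast"`, or an expert id present in `priors`.
#' @return A [pooled_prior()] labelled by `group`.
#' @export
select_community <- function(set, priors, group = "all") {
  if (!inherits(set, "elicitation_set"))
    stopf("select_community: 'set' must be an elicitation_set")
  ids <- vapply(priors, `[[`, character(1), "expert_id")
  roles <- vapply(set$responses, `[[`, character(1), "role")
  names(roles) <- vapply(set$responses, `[[`, character(1), "expert_id")

  keep <- switch(group,
    all = rep(TRUE, length(priors)),
    doctors = roles[ids] == "doctor",
    nurses = roles[ids] == "nurse",
    sceptic = ids == find_extreme_expert(priors, "sceptical"),
    enthusiast = ids == find_extreme_expert(priors, "enthusiastic"),
    ids == group)
  keep[is.na(keep)] <- FALSE
  if (!any(keep))
    stopf("select_community: group '%s' matches no priors", group)
  linear_pool(priors[keep], label = group)
}

#' The full community of priors
#'
#' Convenience wrapper returning the five analysis priors: the pooled
#' panel, the two role subgroups, and the two extreme individuals.
#'
#' @inheritParams select_community
#' @return Named list of [pooled_prior()] objects
#'   (`all`, `doctors`, `nurses`, `sceptic`, `enthusiast`).
#' @export
community_of_priors <- function(set, priors) {
  groups <- c("all", "doctors", "nurses", "sceptic", "enthusiast")
  stats::setNames(lapply(groups, function(g) select_community(set, priors, g)),
                  groups)
}

#' Read / write a pooled prior as JSON
#'
#' @param pool A [pooled_prior()].
#' @param path File path.
#' @return `write_pool`: `path` invisibly; `read_pool`: a `pooled_prior`.
#' @export
write_pool <- function(pool, path) {
  doc <- list(label = pool$label, weights = pool$weights,
              components = lapply(pool$components, function(p)
                list(expert_id = p$expert_id, mean_O = p$mean_O, sd_O = p$sd_O,
                     mean_E = p$mean_E, sd_E = p$sd_E, rho = p$rho)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  doc <- jsonlite::read_json(path)
  comps <- lapply(doc$components, function(p)
    sensitivity_prior(p$expert_id, p$mean_O, p$sd_O, p$mean_E, p$sd_E, p$rho))
  linear_pool(comps, weights = as.numeric(unlist(doc$weights)), label = doc$label)
}
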