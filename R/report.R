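# Density strips and the community-of-priors comparison report.
#
# A density strip renders a full 1-D distribution as a shaded bar whose
# darkness is proportional to the estimated density, darkest at the mode;
# stacking one strip per prior gives the community comparison at a glance.
# Strips are numeric objects (grid + intensity), so tests and downstream
# consumers work with numbers rather than pixels.

#' Build a density strip from posterior draws
#'
#' Kernel density estimate on a fixed grid, max-normalised so the modal
#' grid cell has intensity exactly 1.  Degenerate samples (all draws
#' equal) produce a single saturated cell at the nearest grid point.
#'
#' @param draws Numeric draws of the treatment difference (>= 1000 for a
#'   stable strip; fewer triggers a warning).
#' @param grid Ordered evaluation grid; the default `[-0.3, 0.4]` with 701
#'   points covers the plausible utility-difference range.
#' @param mcid Threshold for the annotated exceedance probability.
#' @return An object of class `density_strip`: `grid`, `intensity` (in
#'   `[0, 1]`, max 1), and `annotations` (mean, 2.5/97.5 percentiles,
#'   `p_mcid`).
#' @export
make_density_strip <- function(draws, grid = seq(-0.3, 0.4, length.out = 701),
                               mcid = 0.03) {
  draws <- as.numeric(draws)
  if (!length(draws)) stopf("make_density_strip: no draws")
  if (length(draws) < 1000)
    warnf("make_density_strip: only %d draws; strip may be noisy", length(draws))
  if (is.unsorted(grid)) stopf("make_density_strip: 'grid' must be increasing")
  if (stats::sd(draws) == 0) {
    intensity <- numeric(length(grid))
    intensity[which.min(abs(grid - draws[1]))] <- 1
  } else {
    kde <- stats::density(draws, from = min(grid), to = max(grid), n = length(grid))
    dens <- stats::approx(kde$x, kde$y, xout = grid, rule = 2)$y
    intensity <- dens / max(dens)
  }
  ann <- list(mean = mean(draws),
              ci_low = unname(stats::quantile(draws, 0.025)),
              ci_high = unname(stats::quantile(draws, 0.975)),
              p_mcid = mean(draws >= mcid), mcid = mcid)
  structure(list(grid = grid, intensity = intensity, annotations = ann),
            class = "density_strip")
}

#' @export
print.density_strip <- function(x, ...) {
  a <- x$annotations
  cat(sprintf("Density strip on [%g, %g] (%d cells): mean %.3f, 95%% (%.3f, %.3f), P(>= %.3g) = %.3f\n",
              min(x$grid), max(x$grid), length(x$grid),
              a$mean, a$ci_low, a$ci_high, a$mcid, a$p_mcid))
  invisible(x)
}

draw_strip <- function(strip, y, height = 0.8, label = NULL) {
  g <- strip$grid
  n <- length(g)
  cols <- grDevices::gray(1 - strip$intensity)
  graphics::rect(g[-n], y - height / 2, g[-1], y + height / 2,
                 col = cols[-n], border = NA)
  a <- strip$annotations
  graphics::segments(a$mean, y - height / 2, a$mean, y + height / 2, lwd = 2)
  graphics::points(c(a$ci_low, a$ci_high), c(y, y), pch = "|")
  if (!is.null(label))
    graphics::mtext(label, side = 2, at = y, las = 1, line = 0.5, cex = 0.8)
}

#' @export
plot.density_strip <- function(x, main = "Density strip", ...) {
  graphics::plot(range(x$grid), c(0, 1), type = "n", yaxt = "n",
                 xlab = "Treatment difference (utility)", ylab = "",
                 main = main, ...)
  draw_strip(x, 0.5)
  invisible(x)
}

#' Community-of-priors comparison report
#'
#' Assembles one summary row and one density strip per labelled result —
#' typically complete-case and MAR comparators plus the MNAR fits under
#' the pooled, subgroup and extreme-expert priors — into a single object
#' that prints as a table, plots as stacked strips, and round-trips
#' through JSON.
#'
#' @param results Named list (unique labels) of fits: `pmm_bayes`,
#'   [pmm_fit()] objects, or raw numeric draw vectors.
#' @param mcid Exceedance threshold for `p_mcid`.
#' @param grid Shared strip grid.
#' @return An object of class `pmm_report`: `table` (data frame with
#'   `label`, `mean`, `ci_low`, `ci_high`, `p_mcid`, `max_rhat`,
#'   `n_draws`) and `strips` (named list of [make_density_strip()]
#'   results).
#' @export
community_report <- function(results, mcid = 0.03,
                             grid = seq(-0.3, 0.4, length.out = 701)) {
  if (!is.list(results) || !length(results)) stopf("community_report: no results")
  labels <- names(results)
  if (is.null(labels) || any(!nzchar(labels)))
    stopf("community_report: results must be a fully named list")
  if (anyDuplicated(labels))
    stopf("community_report: duplicate label(s): %s",
          paste(unique(labels[duplicated(labels)]), collapse = ", "))

  rows <- list(); strips <- list()
  for (lab in labels) {
    r <- results[[lab]]
    if (inherits(r, "pmm_fit")) r <- if (r$method == "bayes") r$fit else
      simulate(r, nsim = 10000, seed = 1)
    if (inherits(r, "pmm_bayes")) {
      draws <- r$draws$Delta
      max_rhat <- max(r$diagnostics$rhat, na.rm = TRUE)
    } else {
      draws <- as.numeric(r)
      max_rhat <- NA_real_
    }
    strip <- make_density_strip(draws, grid = grid, mcid = mcid)
    a <- strip$annotations
    rows[[lab]] <- data.frame(label = lab, mean = a$mean,
                              ci_low = a$ci_low, ci_high = a$ci_high,
                              p_mcid = a$p_mcid, max_rhat = max_rhat,
                              n_draws = length(draws),
                              stringsAsFactors = FALSE)
    strips[[lab]] <- strip
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 strips = strips, mcid = mcid, grid = grid),
            class = "pmm_report")
}

#' @export
print.pmm_report <- function(x, digits = 3, ...) {
  cat(sprintf("Community-of-priors report (%d model runs; MCID %.3g)\n",
              nrow(x$table), x$mcid))
  tab <- x$table
  tab$mean <- round(tab$mean, digits)
  tab$ci_low <- round(tab$ci_low, digits)
  tab$ci_high <- round(tab$ci_high, digits)
  tab$p_mcid <- round(tab$p_mcid, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
plot.pmm_report <- function(x, ...) {
  n <- nrow(x$table)
  op <- graphics::par(mar = c(4, 9, 3, 1))
  on.exit(graphics::par(op))
  graphics::plot(range(x$grid), c(0.5, n + 0.5), type = "n", yaxt = "n",
                 xlab = "Difference in mean QoL (eEVAR - OPEN)", ylab = "",
                 main = "Treatment difference under the community of priors", ...)
  graphics::abline(v = 0, lty = 3)
  graphics::abline(v = x$mcid, lty = 2, col = "grey40")
  for (i in seq_len(n)) {
    lab <- x$table$label[i]
    draw_strip(x$strips[[lab]], n - i + 1,
               label = sprintf("%s (%.0f%%)", lab, 100 * x$table$p_mcid[i]))
  }
  invisible(x)
}

#' Write / read a community report as JSON
#'
#' The JSON twin carries the summary table, the shared grid, and each
#' strip's intensities and annotations; `read_report_json` reconstructs
#' the `pmm_report` losslessly up to floating-point serialisation.
#'
#' @param report A [community_report()] result.
#' @param path File path.
#' @return `write_report_json`: `path` invisibly; `read_report_json`: a
#'   `pmm_report`.
#' @export
write_report_json <- function(report, path) {
  doc <- list(mcid = report$mcid, grid = report$grid,
              table = report$table,
              strips = lapply(report$strips, function(s)
                list(intensity = s$intensity, annotations = s$annotations)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(path)
}

#' @rdname write_report_json
#' @export
read_report_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  grid <- as.numeric(doc$grid)
  strips <- lapply(doc$strips, function(s) {
    structure(list(grid = grid, intensity = as.numeric(s$intensity),
                   annotations = as.list(s$annotations)),
              class = "density_strip")
  })
  tab <- as.data.frame(doc$table)
  # an all-NA diagnostic column serialises to nulls and drops on read
  tab$max_rhat <- if (is.null(tab$max_rhat)) rep(NA_real_, nrow(tab)) else
    as.numeric(tab$max_rhat)
  structure(list(table = tab, strips = strips,
                 mcid = doc$mcid, grid = grid),
            class = "pmm_report")
}

#' Individual and pooled marginal prior curves
#'
#' Evaluates each expert's marginal prior density for the requested arm's
#' sensitivity parameter on a common grid, together with the pooled
#' mixture curve (the weighted pointwise sum of the component curves).
#'
#' @param priors List of [sensitivity_prior()] objects.
#' @param pool Optional [pooled_prior()]; defaults to the equal-weight
#'   pool of `priors`.
#' @param arm `"O"` or `"E"`.
#' @param grid Evaluation grid on the utility scale.
#' @return An object of class `prior_overlay`: `grid`, `components`
#'   (matrix, one column per expert), `pooled` (vector), `arm`.
#' @export
prior_overlay <- function(priors, pool = NULL, arm = c("O", "E"),
                          grid = seq(-0.6, 0.6, length.out = 401)) {
  arm <- match.arg(arm)
  if (!length(priors)) stopf("prior_overlay: no priors")
  if (is.null(pool)) pool <- linear_pool(priors)
  comp <- vapply(pool$components, function(p) {
    m <- p[[paste0("mean_", arm)]]; s <- p[[paste0("sd_", arm)]]
    if (s <= 0) stopf("prior_overlay: component '%s' has zero sd", p$expert_id)
    stats::dnorm(grid, m, s)
  }, numeric(length(grid)))
  colnames(comp) <- vapply(pool$components, `[[`, character(1), "expert_id")
  pooled <- as.numeric(comp %*% pool$weights)
  structure(list(grid = grid, components = comp, pooled = pooled, arm = arm,
                 label = pool$label),
            class = "prior_overlay")
}

#' @export
plot.prior_overlay <- function(x, ...) {
  graphics::matplot(x$grid, x$components, type = "l", lty = 1, col = "grey70",
                    xlab = bquote(delta[.(x$arm)] ~ "(utility)"),
                    ylab = "Prior density",
                    main = sprintf("Individual and pooled priors (%s arm)",
                                   if (x$arm == "O") "open repair" else "eEVAR"), ...)
  graphics::lines(x$grid, x$pooled, lwd = 3)
  invisible(x)
}
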