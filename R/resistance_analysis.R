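#' Fit a resistance coefficient from one force-extension trace
#'
#' Ordinary least-squares slope (intercept free) of spring force against
#' dummy displacement, restricted to samples with displacement not exceeding
#' `fit_range` (default 2.5 A, within the range of nonbonded interactions so
#' pulling probes the CA near its equilibrium position rather than
#' unfolding).  The slope, in pN/A, is the residue's resistance coefficient.
#'
#' @param trace an `fe_trace` from [run_smd()].
#' @param fit_range regression window in A.
#' @return slope in pN/A.
#' @export
fit_resistance <- function(trace, fit_range = 2.5) {
  s <- trace$samples
  s <- s[s$displacement <= fit_range, ]
  if (nrow(s) < 3) {
    stop("insufficient data: fewer than 3 samples within fit range ",
         fit_range, " A")
  }
  fit <- stats::lm(force_pN ~ displacement, data = s)
  unname(stats::coef(fit)[2])
}

#' Aggregate replicate slopes
#'
#' @param slopes numeric vector of per-replicate resistance coefficients
#'   (pN/A).
#' @return list with `mean`, `sem` (sample sd / sqrt(n); 0 with a warning
#'   for n = 1) and `n`.
#' @export
aggregate_replicates <- function(slopes) {
  if (length(slopes) == 0) stop("no slopes to aggregate")
  n <- length(slopes)
  if (n == 1) {
    warning("single replicate: SEM reported as 0")
    return(list(mean = slopes, sem = 0, n = 1L))
  }
  list(mean = mean(slopes), sem = stats::sd(slopes) / sqrt(n), n = n)
}

#' Build a per-residue resistance profile from a surface scan
#'
#' Fits every replicate trace, aggregates per residue, and classifies.
#'
#' @param scan_results named list residue -> list of `fe_trace`, from
#'   [scan_surface()].
#' @param fit_range regression window in A (default 2.5).
#' @param low,high classification thresholds in pN/A.
#' @return a `resistance_profile`: data.frame with columns `residue_index`,
#'   `mean_coefficient`, `sem`, `n_replicates`, `class`.
#' @export
resistance_profile <- function(scan_results, fit_range = 2.5,
                               low = 100, high = 300) {
  stopifnot(length(scan_results) > 0)
  rows <- lapply(names(scan_results), function(r) {
    slopes <- vapply(scan_results[[r]], fit_resistance, numeric(1),
                     fit_range = fit_range)
    agg <- aggregate_replicates(slopes)
    data.frame(residue_index = as.integer(r), mean_coefficient = agg$mean,
               sem = agg$sem, n_replicates = agg$n)
  })
  prof <- do.call(rbind, rows)
  prof <- prof[order(prof$residue_index), ]
  rownames(prof) <- NULL
  class(prof) <- c("resistance_profile", "data.frame")
  classify_residues(prof, low = low, high = high)
}

#' Classify residues by resistance coefficient
#'
#' Strict thresholds: mean below `low` is class "low" (mobile), above `high`
#' is "high" (static); the closed interval maps to "mid".
#'
#' @param profile a `resistance_profile` (or data.frame with
#'   `mean_coefficient`).
#' @param low,high thresholds in pN/A (low < high; defaults 100 and 300).
#' @return the profile with an updated `class` column.
#' @export
classify_residues <- function(profile, low = 100, high = 300) {
  if (!(low < high)) stop("thresholds must satisfy low < high")
  m <- profile$mean_coefficient
  profile$class <- ifelse(m < low, "low", ifelse(m > high, "high", "mid"))
  if (!inherits(profile, "resistance_profile")) {
    class(profile) <- c("resistance_profile", class(profile))
  }
  profile
}

#' Detect stability patches
#'
#' Surface residues at or above `patch_threshold` are clustered by spatial
#' adjacency: two residues are linked when their CA atoms are within
#' `linkage_cutoff`; connected components of at least `min_size` residues
#' are reported as patches, sorted by descending mean coefficient.
#'
#' @param structure a [mol_structure()].
#' @param profile a `resistance_profile`.
#' @param patch_threshold minimum mean coefficient (pN/A) for membership.
#' @param linkage_cutoff CA-CA adjacency cutoff in A (default 8).
#' @param min_size minimum residues per patch (default 2).
#' @return list of `stability_patch` objects (possibly empty), each with
#'   `residue_indices`, `mean_coefficient`, `centroid`.
#' @export
find_stability_patches <- function(structure, profile, patch_threshold,
                                   linkage_cutoff = 8, min_size = 2) {
  cand <- profile$residue_index[profile$mean_coefficient >= patch_threshold]
  if (length(cand) < min_size) return(list())
  ca <- t(vapply(cand, function(r) coords(structure)[ca_row(structure, r), ],
                 numeric(3)))
  d <- as.matrix(stats::dist(ca))
  adj <- d <= linkage_cutoff
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  patches <- lapply(seq_len(comp$no), function(cid) {
    members <- cand[comp$membership == cid]
    if (length(members) < min_size) return(NULL)
    mc <- profile$mean_coefficient[match(members, profile$residue_index)]
    structure(list(residue_indices = sort(members),
                   mean_coefficient = mean(mc),
                   centroid = colMeans(ca[comp$membership == cid, , drop = FALSE])),
              class = "stability_patch")
  })
  patches <- Filter(Negate(is.null), patches)
  patches[order(vapply(patches, `[[`, numeric(1), "mean_coefficient"),
                decreasing = TRUE)]
}

#' @export
print.stability_patch <- function(x, ...) {
  cat(sprintf("<stability_patch> %d residues (%s), mean %.1f pN/A\n",
              length(x$residue_indices),
              paste(x$residue_indices, collapse = ","), x$mean_coefficient))
  invisible(x)
}

#' Conformation-pair difference profile
#'
#' Per-residue change in mean resistance coefficient between two states
#' (state B minus state A), restricted to the residues surface-exposed in
#' both.  Changes strictly beyond the threshold (default 70 pN/A) are
#' classified "stabilized" (positive) or "destabilized" (negative);
#' everything else is "unchanged".
#'
#' @param profile_a,profile_b `resistance_profile`s of states A and B.
#' @param threshold classification threshold in pN/A.
#' @return a `delta_profile` data.frame with `residue_index`, `delta`,
#'   `class`.
#' @export
delta_profile <- function(profile_a, profile_b, threshold = 70) {
  common <- intersect(profile_a$residue_index, profile_b$residue_index)
  if (length(common) == 0) stop("no residues shared between the two profiles")
  a <- profile_a$mean_coefficient[match(common, profile_a$residue_index)]
  b <- profile_b$mean_coefficient[match(common, profile_b$residue_index)]
  delta <- b - a
  cls <- ifelse(delta > threshold, "stabilized",
                ifelse(delta < -threshold, "destabilized", "unchanged"))
  out <- data.frame(residue_index = common, delta = delta, class = cls)
  out <- out[order(out$residue_index), ]
  rownames(out) <- NULL
  class(out) <- c("delta_profile", "data.frame")
  attr(out, "threshold") <- threshold
  out
}

#' Pearson correlation with input validation
#'
#' @param x,y numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return sample Pearson correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: zero variance in input")
  }
  stats::cor(x, y)
}

#' Export a resistance or delta profile as TSV text
#'
#' @param profile a `resistance_profile` or `delta_profile`.
#' @return character scalar of TSV text.
#' @export
profile_tsv <- function(profile) {
  df <- as.data.frame(profile)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) {
    ifelse(v == round(v), format(v, trim = TRUE, scientific = FALSE),
           sprintf("%.4f", v))
  })
  paste(c(paste(names(df), collapse = "\t"),
          apply(df, 1, paste, collapse = "\t"), ""),
        collapse = "\n")
}

#' Export stability patches as JSON text
#'
#' @param patches list from [find_stability_patches()].
#' @return character scalar of JSON.
#' @export
patches_json <- function(patches) {
  jsonlite::toJSON(lapply(patches, function(p) {
    list(residue_indices = p$residue_indices,
         mean_coefficient = p$mean_coefficient,
         centroid = p$centroid)
  }), auto_unbox = FALSE, digits = NA)
}
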