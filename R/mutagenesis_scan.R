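#' Two-tailed unpaired t-test (pooled variance)
#'
#' Student's two-sample t with pooled variance and n_a + n_b - 2 degrees of
#' freedom (Welch's unequal-variance form available via `welch = TRUE`).
#' Degenerate inputs follow the conventions: two identical constant samples
#' give t = 0, p = 1; zero pooled variance with unequal means gives the
#' p -> 0 limit with a warning.
#'
#' @param sample_a,sample_b numeric vectors, each of length >= 2.
#' @param welch use Welch's unequal-variance test instead of pooled.
#' @return list with `t`, `p`, `df`.
#' @export
two_tailed_unpaired_t_test <- function(sample_a, sample_b, welch = FALSE) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2,
            all(is.finite(sample_a)), all(is.finite(sample_b)))
  if (stats::sd(sample_a) == 0 && stats::sd(sample_b) == 0) {
    if (mean(sample_a) == mean(sample_b)) {
      return(list(t = 0, p = 1, df = length(sample_a) + length(sample_b) - 2))
    }
    warning("zero pooled variance with unequal means: p -> 0 limit")
    return(list(t = sign(mean(sample_a) - mean(sample_b)) * Inf, p = 0,
                df = length(sample_a) + length(sample_b) - 2))
  }
  ht <- stats::t.test(sample_a, sample_b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter))
}

#' Alanine scan around a focus residue
#'
#' Identifies the residues whose heavy atoms lie within `neighbor_radius` of
#' the focus residue's side chain (alanines and glycines excluded, the focus
#' itself included), and for each one: mutates it to alanine, rebuilds the
#' force field on the mutant structure, re-equilibrates with an extra
#' unconstrained stage, runs replicate pulls on the focus residue's CA, and
#' compares the mutant slope distribution against wild type with a
#' two-tailed unpaired t-test.
#'
#' @param structure equilibrated wild-type [mol_structure()].
#' @param focus_residue residue whose resistance coefficient is probed.
#' @param backend_builder function(structure) -> [ff_backend()]; called for
#'   the wild type and for every mutant.
#' @param neighbor_radius heavy-atom contact radius in A (default 5).
#' @param protocol_config list of protocol parameters; see
#'   [default_protocol_config()].
#' @param extra_equilibration_ps unconstrained mutant re-equilibration
#'   window (default 100 ps).
#' @param alpha significance level (default 0.05).
#' @param direction optional explicit pull direction passed through to
#'   [build_pull_spec()].
#' @return list of `mutant_scan_result` objects; the wild-type slopes are in
#'   `attr(, "wt_slopes")`, failed mutations in `attr(, "failures")`.
#' @export
scan_neighbors <- function(structure, focus_residue, backend_builder,
                           neighbor_radius = 5,
                           protocol_config = default_protocol_config(),
                           extra_equilibration_ps = 100, alpha = 0.05,
                           direction = NULL) {
  cfg <- utils::modifyList(default_protocol_config(), protocol_config)
  spec <- integrator_spec(cfg$timestep_fs, cfg$friction_ps, cfg$temperature)
  a <- structure$atoms
  focus_rows <- which(a$residue_index == focus_residue)
  if (length(focus_rows) == 0) stop("no residue with index ", focus_residue)
  side <- focus_rows[!(a$atom_name[focus_rows] %in% .backbone_atom_names) &
                       toupper(a$element[focus_rows]) != "H"]
  if (length(side) == 0) side <- focus_rows  # Gly-like focus: use whole residue
  xyz <- coords(structure)
  heavy <- which(toupper(a$element) != "H")
  d2 <- vapply(heavy, function(i) {
    min(colSums((t(xyz[side, , drop = FALSE]) - xyz[i, ])^2))
  }, numeric(1))
  near_res <- unique(a$residue_index[heavy[d2 <= neighbor_radius^2]])
  targets <- sort(unique(c(focus_residue, near_res)))
  keep <- vapply(targets, function(r) {
    nm <- a$residue_name[a$residue_index == r][1]
    nm %in% .standard_residues && !(nm %in% c("ALA", "GLY"))
  }, logical(1))
  targets <- targets[keep]
  if (length(targets) == 0) stop("no mutable residues within ",
                                 neighbor_radius, " A of residue ", focus_residue)

  run_focus_pulls <- function(struct, seed_base) {
    bk <- backend_builder(struct)
    ps <- build_pull_spec(struct, focus_residue,
                          spring_constant = cfg$spring_constant,
                          pull_velocity = cfg$pull_velocity,
                          max_dummy_displacement = cfg$max_dummy_displacement,
                          temperature = cfg$temperature,
                          neighborhood_radius = cfg$neighborhood_radius,
                          free_radius = cfg$free_radius,
                          direction = direction)
    traces <- withCallingHandlers(
      run_replicates(struct, ps, bk, n_replicates = cfg$n_replicates,
                     seed_base = seed_base, spec = spec,
                     sample_every = cfg$sample_every,
                     freeze_outside = cfg$freeze_outside),
      warning = function(w) invokeRestart("muffleWarning"))
    vapply(traces, fit_resistance, numeric(1), fit_range = cfg$fit_range)
  }

  wt_slopes <- run_focus_pulls(structure, residue_seed_base(cfg$seed_base, 0))
  wt_agg <- aggregate_replicates(wt_slopes)

  results <- list()
  failures <- list()
  for (r in targets) {
    res <- tryCatch({
      orig_name <- a$residue_name[a$residue_index == r][1]
      mut <- mutate_to_alanine(structure, r)
      bk_mut <- backend_builder(mut)
      mut <- equilibrate(mut, bk_mut,
                         schedule = list(list(restrain = "none",
                                              duration_ps = extra_equilibration_ps)),
                         spec = {
                           s <- spec
                           s$seed <- residue_seed_base(cfg$seed_base, r) + 7919
                           s
                         },
                         minimize = FALSE)
      slopes <- run_focus_pulls(mut, residue_seed_base(cfg$seed_base, r))
      agg <- aggregate_replicates(slopes)
      tt <- two_tailed_unpaired_t_test(wt_slopes, slopes)
      structure(list(mutated_residue = r, original_name = orig_name,
                     focus_residue = focus_residue,
                     wt_mean = wt_agg$mean, wt_sem = wt_agg$sem,
                     mut_mean = agg$mean, mut_sem = agg$sem,
                     n_wt = wt_agg$n, n_mut = agg$n,
                     t_statistic = tt$t, p_value = tt$p,
                     significant = tt$p < alpha,
                     mut_slopes = slopes),
                class = "mutant_scan_result")
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[as.character(r)]] <- conditionMessage(res)
    } else {
      results[[paste0(res$original_name, r)]] <- res
    }
  }
  attr(results, "wt_slopes") <- wt_slopes
  if (length(failures) > 0) attr(results, "failures") <- failures
  results
}

#' @export
print.mutant_scan_result <- function(x, ...) {
  cat(sprintf("<mutant_scan_result> %s%d->Ala: focus %d, WT %.1f+/-%.1f vs mut %.1f+/-%.1f pN/A, p = %.3g%s\n",
              x$original_name, x$mutated_residue, x$focus_residue,
              x$wt_mean, x$wt_sem, x$mut_mean, x$mut_sem, x$p_value,
              if (x$significant) " *" else " (ns)"))
  invisible(x)
}

#' Tabulate an alanine-scan result list
#'
#' @param results list from [scan_neighbors()].
#' @return data.frame, one row per mutant.
#' @export
mutant_scan_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    data.frame(mutation = paste0(x$original_name, x$mutated_residue, "A"),
               focus_residue = x$focus_residue,
               wt_mean = x$wt_mean, wt_sem = x$wt_sem,
               mut_mean = x$mut_mean, mut_sem = x$mut_sem,
               n_wt = x$n_wt, n_mut = x$n_mut,
               t = x$t_statistic, p = x$p_value,
               significant = x$significant, row.names = NULL)
  }))
}
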