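#' Scenario specification for synthetic block-activation data
#'
#' A `scenario_spec` is the generative description of a synthetic multi-subject
#' experiment: a tuning matrix holding each region's mean activation per task
#' (the population signal), plus state-specific noise covariances for task and
#' rest blocks (the population noise). The correlation of tuning rows is the
#' population signal correlation (SC); the covariances, converted to
#' correlation, are the population rest/task noise correlations (rNC/tNC).
#'
#' @param n_subjects number of subjects to generate.
#' @param n_regions number of parcels/regions.
#' @param n_tasks number of task conditions (default 26).
#' @param blocks_per_task blocks per task per subject (default 16, minimum 2).
#' @param rest_blocks number of rest blocks interleaved in the run (default 16;
#'   matching the task block count equalizes estimator variance between rest
#'   and per-task noise-correlation estimates).
#' @param tuning `n_regions x n_tasks` matrix of mean activations (arbitrary
#'   units). Defaults to standard-normal tuning drawn from the seed.
#' @param sigma_rest `n_regions x n_regions` noise covariance of rest blocks.
#' @param sigma_task noise covariance of task blocks: a single matrix, or a
#'   list of `n_tasks` matrices for task-specific noise structure.
#' @param subject_tuning_sd standard deviation of between-subject jitter added
#'   to the tuning matrix (jitter applies to tuning only, not covariance).
#' @param seed integer master seed for the scenario.
#' @return an object of class `scenario_spec`.
#' @seealso [generate_subject_betas()], [generate_dataset()],
#'   [make_alignment_scenarios()]
#' @export
scenario_spec <- function(n_subjects, n_regions, n_tasks = 26L,
                          blocks_per_task = 16L, rest_blocks = 16L,
                          tuning = NULL, sigma_rest = diag(n_regions),
                          sigma_task = diag(n_regions),
                          subject_tuning_sd = 0, seed = 1L) {
  stopifnot(is_count(n_subjects), is_count(n_regions), is_count(n_tasks, 2L),
            is_count(blocks_per_task, 2L), is_count(rest_blocks, 0L),
            is.numeric(subject_tuning_sd), subject_tuning_sd >= 0,
            is_count(abs(seed), 0L))
  if (is.null(tuning)) {
    tuning <- with_seed(derive_seed(seed, "tuning"),
                        matrix(stats::rnorm(n_regions * n_tasks), n_regions, n_tasks))
  }
  stopifnot(is.matrix(tuning), nrow(tuning) == n_regions, ncol(tuning) == n_tasks)
  sigma_rest <- symmetrize(sigma_rest, what = "sigma_rest")
  stopifnot(nrow(sigma_rest) == n_regions)
  if (!is.list(sigma_task)) sigma_task <- list(sigma_task)
  if (!length(sigma_task) %in% c(1L, n_tasks)) {
    stop("sigma_task must be a single matrix or one matrix per task")
  }
  sigma_task <- lapply(sigma_task, symmetrize, what = "sigma_task")
  for (s in sigma_task) stopifnot(nrow(s) == n_regions)
  # fail early on non-PSD covariances
  cov_factor(sigma_rest)
  lapply(sigma_task, cov_factor)

  region_labels <- sprintf("R%03d", seq_len(n_regions))
  task_labels <- sprintf("task%02d", seq_len(n_tasks))
  dimnames(tuning) <- list(region_labels, task_labels)
  dimnames(sigma_rest) <- list(region_labels, region_labels)
  sigma_task <- lapply(sigma_task, `dimnames<-`, list(region_labels, region_labels))

  structure(list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    n_tasks = as.integer(n_tasks), blocks_per_task = as.integer(blocks_per_task),
    rest_blocks = as.integer(rest_blocks), tuning = tuning,
    sigma_rest = sigma_rest, sigma_task = sigma_task,
    subject_tuning_sd = subject_tuning_sd, seed = as.integer(seed),
    region_labels = region_labels, task_labels = task_labels
  ), class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "scenario_spec: %d subjects, %d regions, %d tasks x %d blocks + %d rest blocks (seed %d)\n",
    x$n_subjects, x$n_regions, x$n_tasks, x$blocks_per_task, x$rest_blocks, x$seed))
  invisible(x)
}

#' Build a network-structured covariance matrix
#'
#' Constructs a block-structured correlation matrix with correlation
#' `within_r` for region pairs inside the same network and `between_r` across
#' networks, then scales it by per-region variances. This is the canonical way
#' to obtain population noise-covariance targets whose network structure
#' mirrors resting-state functional connectivity.
#'
#' @param partition region-to-network assignment: a character/factor vector
#'   with one network label per region, or a `network_partition` object.
#' @param within_r correlation within networks.
#' @param between_r correlation between networks; requires
#'   `-1 < between_r <= within_r < 1`.
#' @param variances per-region positive variances (default all 1).
#' @return a symmetric positive semi-definite covariance matrix.
#' @export
build_structured_covariance <- function(partition, within_r, between_r,
                                        variances = NULL) {
  labels <- if (inherits(partition, "network_partition")) partition$label else partition
  n <- length(labels)
  stopifnot(n >= 2)
  if (!(between_r > -1 && between_r <= within_r && within_r < 1)) {
    stop("require -1 < between_r <= within_r < 1")
  }
  variances <- variances %||% rep(1, n)
  stopifnot(length(variances) == n, all(variances > 0))
  same <- outer(labels, labels, "==")
  r <- ifelse(same, within_r, between_r)
  diag(r) <- 1
  lam <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-10) {
    stop(sprintf(
      "within_r=%.3g / between_r=%.3g yields a non-PSD matrix (smallest eigenvalue %.6g)",
      within_r, between_r, min(lam)))
  }
  d <- sqrt(variances)
  sigma <- r * tcrossprod(d)
  rn <- names(labels) %||% sprintf("R%03d", seq_len(n))
  dimnames(sigma) <- list(rn, rn)
  sigma
}

#' Population signal correlation of a scenario
#'
#' Pearson correlation of the tuning rows: the across-task correlation of
#' mean activations, which is exactly what [compute_sc()] estimates.
#'
#' @param spec a `scenario_spec`.
#' @return a correlation matrix of class `corr_matrix` with role `"SC"`.
#' @export
population_sc <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  corr_matrix(stats::cor(t(spec$tuning)), role = "SC", subject = "population")
}

#' Population noise correlation of a scenario
#'
#' @param spec a `scenario_spec`.
#' @param state `"rest"` or `"task"`; for task-specific covariances the
#'   unweighted mean of per-task correlation matrices is returned (the
#'   population analogue of the task-general tNC).
#' @return a `corr_matrix` with role `"rNC"` or `"tNC"`.
#' @export
population_nc <- function(spec, state = c("rest", "task")) {
  stopifnot(inherits(spec, "scenario_spec"))
  state <- match.arg(state)
  if (state == "rest") {
    return(corr_matrix(stats::cov2cor(spec$sigma_rest), role = "rNC",
                       subject = "population"))
  }
  mats <- lapply(spec$sigma_task, stats::cov2cor)
  corr_matrix(Reduce(`+`, mats) / length(mats), role = "tNC",
              subject = "population")
}

#' Construct aligned and anti-aligned task-noise scenarios
#'
#' Starting from a base scenario, builds a pair of scenarios that share the
#' tuning (hence the population SC) and the rest-noise covariance, but whose
#' task-noise correlations are shifted entrywise by `delta_magnitude` in the
#' direction of the population SC sign (aligned scenario) or opposite to it
#' (anti-aligned scenario). Marginal variances are identical across the two
#' scenarios, so any downstream decoding difference cannot come from
#' univariate signal strength.
#'
#' Pairs whose population SC magnitude is at most `sc_tol` are treated as
#' zero-signal pairs and left unshifted; the shift is only defined on the
#' nonzero-SC pair set. Large constant-magnitude shifts can make a correlation
#' matrix indefinite; such violations are an error unless `repair = TRUE`, in
#' which case eigenvalues are clipped at zero, the matrix is re-normalized to
#' unit diagonal, and a message reports the repair.
#'
#' @param base_spec a `scenario_spec` providing tuning and `sigma_rest`.
#' @param delta_magnitude size of the correlation shift (>= 0).
#' @param sc_tol SC magnitudes at or below this are treated as zero signal.
#' @param repair if `TRUE`, repair non-PSD shifted matrices by eigenvalue
#'   clipping (logged); if `FALSE` (default), non-PSD shifts are an error.
#' @return a list with elements `aligned` and `anti_aligned`, both
#'   `scenario_spec` objects.
#' @export
make_alignment_scenarios <- function(base_spec, delta_magnitude,
                                     sc_tol = 0.1, repair = FALSE) {
  stopifnot(inherits(base_spec, "scenario_spec"),
            is.numeric(delta_magnitude), delta_magnitude >= 0)
  sc <- unclass_corr(population_sc(base_spec))
  sgn <- sign(sc) * (abs(sc) > sc_tol)
  diag(sgn) <- 0
  if (delta_magnitude > 0 && all(sgn == 0)) {
    stop("base_spec tuning yields no pairs with |SC| > sc_tol; nothing to shift")
  }
  r_rest <- stats::cov2cor(base_spec$sigma_rest)
  v <- diag(base_spec$sigma_rest)

  shifted <- function(direction, tag) {
    r <- r_rest + direction * delta_magnitude * sgn
    r <- pmin(pmax(r, -0.999), 0.999)
    diag(r) <- 1
    lam <- eigen(r, symmetric = TRUE, only.values = TRUE)$values
    if (min(lam) < -1e-10) {
      if (!repair) {
        stop(sprintf(
          "%s shift of %.3g gives a non-PSD task correlation (smallest eigenvalue %.6g); reduce delta_magnitude or set repair = TRUE",
          tag, delta_magnitude, min(lam)))
      }
      e <- eigen(r, symmetric = TRUE)
      r <- e$vectors %*% (pmax(e$values, 0) * t(e$vectors))
      d <- sqrt(diag(r))
      r <- r / tcrossprod(d)
      message(sprintf("%s scenario: repaired non-PSD task correlation by eigenvalue clipping (smallest eigenvalue was %.6g)",
                      tag, min(lam)))
    }
    r * tcrossprod(sqrt(v))
  }

  build <- function(sigma_task) {
    spec <- base_spec
    spec$sigma_task <- list(symmetrize(sigma_task, tol = 1e-8))
    spec
  }
  list(aligned = build(shifted(+1, "aligned")),
       anti_aligned = build(shifted(-1, "anti-aligned")))
}

#' Synthetic scenario with an explicit coding-axis noise geometry
#'
#' Constructs the canonical study scenario for alignment analyses. Regions
#' are organised into *systems* of two modules each: all regions of a system
#' share one orthogonal task-tuning axis pattern, which the first module
#' carries positively and the second negatively, plus a weaker system-common
#' tuning pattern carried positively by both modules. Within-module signal
#' correlation is therefore +1, cross-module (within-system) SC is clearly
#' negative, and between-system SC is zero. Rest noise is a factor model:
#' a global component, a system-shared component with uniform loadings
#' (collinear with the common-mode *signal* but orthogonal to the bipolar
#' axis), a component along the coding axis itself, and private noise
#' filling every region's variance to 1.
#'
#' Shifting the task-noise correlation entrywise along the SC sign (see
#' [make_alignment_scenarios()]) is then exactly equivalent to strengthening
#' (aligned) or weakening (anti-aligned) the coding-axis noise component, so
#' both shifted scenarios remain proper factor models with matched unit
#' variances; `var_axis` must be at least the intended `delta_magnitude` for
#' the anti-aligned shift to stay positive semi-definite. Tuning is purely
#' shared (no region-private component and no subject jitter by default):
#' under variance matching, a private tuning channel hands the aligned
#' scenario a spuriously clean private-noise subspace that a
#' covariance-aware decoder can exploit, which would confound the
#' block-shuffle control.
#'
#' The returned partition labels *modules* (two per system), so
#' [network_matched_cliques()] on a module pair yields cliques mixing both
#' signs of the coding axis.
#'
#' @param n_subjects number of subjects (default 24).
#' @param n_systems number of bipolar systems (default 6; two modules each).
#' @param regions_per_module regions per module (default 5, so 60 regions).
#' @param n_tasks,blocks_per_task,rest_blocks block design (defaults
#'   26/16/16); requires `n_tasks >= 2 * n_systems`.
#' @param common_scale weight of the system-common tuning pattern (default
#'   0.7). This common-mode signal component lies on the system-shared noise
#'   direction, so decoding it benefits from knowledge of the correlation
#'   structure - the component the block-shuffle control destroys.
#' @param subject_tuning_sd between-subject tuning jitter (default 0; see
#'   above).
#' @param var_system variance of the system-shared noise component
#'   (default 0.45).
#' @param var_axis variance of the coding-axis noise component (default
#'   0.25).
#' @param var_global variance of the global noise component (default 0.05).
#' @param seed integer master seed.
#' @return list with `spec` (a [scenario_spec()] whose `sigma_task` equals
#'   `sigma_rest`, ready for [make_alignment_scenarios()]), `partition`
#'   (a [network_partition()] at module granularity), and `axis_sign`
#'   (the +/-1 coding-axis pattern per region).
#' @export
signal_axis_scenario <- function(n_subjects = 24L, n_systems = 6L,
                                 regions_per_module = 5L, n_tasks = 26L,
                                 blocks_per_task = 16L, rest_blocks = 16L,
                                 common_scale = 0.7, subject_tuning_sd = 0,
                                 var_system = 0.45, var_axis = 0.25,
                                 var_global = 0.05, seed = 1L) {
  stopifnot(is_count(n_systems), is_count(regions_per_module),
            var_system >= 0, var_axis >= 0, var_global >= 0,
            var_system + var_axis + var_global < 1,
            common_scale >= 0, common_scale < 1, n_tasks > 2 * n_systems)
  n_regions <- 2L * n_systems * regions_per_module
  system_of <- rep(seq_len(n_systems), each = 2 * regions_per_module)
  module_of <- rep(seq_len(2 * n_systems), each = regions_per_module)
  axis_sign <- rep(rep(c(1, -1), each = regions_per_module), n_systems)

  # 2K orthonormal, mean-zero task patterns (one bipolar axis pattern and one
  # common pattern per system); mean-zero keeps Pearson SC identical to the
  # pattern inner products, so cross-system SC is exactly zero
  u <- with_seed(derive_seed(seed, "axis:tuning"), {
    z <- matrix(stats::rnorm(n_tasks * 2 * n_systems), n_tasks, 2 * n_systems)
    z <- sweep(z, 2, colMeans(z))
    qr.Q(qr(z)) * sqrt(n_tasks)
  })
  tuning <- axis_sign * t(u[, system_of, drop = FALSE]) +
    common_scale * t(u[, n_systems + system_of, drop = FALSE])

  same_system <- outer(system_of, system_of, "==")
  sigma <- matrix(var_global, n_regions, n_regions)
  sigma[same_system] <- sigma[same_system] + var_system
  sigma <- sigma + var_axis * tcrossprod(axis_sign) * same_system
  diag(sigma) <- 1
  labels <- sprintf("R%03d", seq_len(n_regions))
  dimnames(sigma) <- list(labels, labels)

  spec <- scenario_spec(
    n_subjects = n_subjects, n_regions = n_regions, n_tasks = n_tasks,
    blocks_per_task = blocks_per_task, rest_blocks = rest_blocks,
    tuning = tuning, sigma_rest = sigma, sigma_task = sigma,
    subject_tuning_sd = subject_tuning_sd, seed = seed)
  list(spec = spec,
       partition = network_partition(labels, sprintf("net%02d", module_of)),
       axis_sign = axis_sign)
}

#' Write / read a scenario specification as JSON
#'
#' @param spec a `scenario_spec`.
#' @param path file path.
#' @return `read_scenario_json` returns a `scenario_spec`;
#'   `write_scenario_json` returns `path` invisibly.
#' @export
write_scenario_json <- function(spec, path) {
  stopifnot(inherits(spec, "scenario_spec"))
  x <- spec[c("n_subjects", "n_regions", "n_tasks", "blocks_per_task",
              "rest_blocks", "subject_tuning_sd", "seed")]
  x$tuning <- unname(spec$tuning)
  x$sigma_rest <- unname(spec$sigma_rest)
  x$sigma_task <- lapply(spec$sigma_task, unname)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_scenario_json
#' @export
read_scenario_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  scenario_spec(
    n_subjects = x$n_subjects, n_regions = x$n_regions, n_tasks = x$n_tasks,
    blocks_per_task = x$blocks_per_task, rest_blocks = x$rest_blocks,
    tuning = as.matrix(x$tuning), sigma_rest = as.matrix(x$sigma_rest),
    sigma_task = if (is.array(x$sigma_task) && length(dim(x$sigma_task)) == 3) {
      lapply(seq_len(dim(x$sigma_task)[1]),
             function(i) as.matrix(x$sigma_task[i, , ]))
    } else if (is.list(x$sigma_task)) {
      lapply(x$sigma_task, function(m) as.matrix(do.call(rbind, lapply(m, unlist))))
    } else {
      list(as.matrix(x$sigma_task))
    },
    subject_tuning_sd = x$subject_tuning_sd, seed = x$seed)
}
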