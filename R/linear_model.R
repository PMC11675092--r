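# Linear statistical network model of state-specific correlations: each
# unit's activity is a linear sum of independent standard-normal components
#   x = x_shared(network) + x_private(unit) + w_drive * s_drive + w_global * g
# with the stimulus drive s_drive present only in the task state. Because the
# model is a pure linear superposition, task-state noise correlations can
# only move in the direction of the existing shared structure — the
# prediction that the empirical signal-noise differential analysis tests.

#' Configuration of the linear statistical network model
#'
#' @param n_networks number of network modules (default 10).
#' @param units_per_network units per module (default 30).
#' @param w_drive weight of the stimulus-drive component (default 0.75).
#' @param w_global weight of the globally shared component (default 0.75).
#' @param n_samples samples to simulate (default 10000).
#' @param drive_topology how the task-state drive is shared:
#'   `"within_network"` (each network has its own drive, the default),
#'   `"global"` (one drive shared by all units), or `"network_subset"`
#'   (per-network drives restricted to `driven_networks`).
#' @param driven_networks integer ids of driven networks (only for
#'   `"network_subset"`).
#' @param seed integer seed for the simulator.
#' @return an object of class `linear_model_config`.
#' @export
linear_model_config <- function(n_networks = 10L, units_per_network = 30L,
                                w_drive = 0.75, w_global = 0.75,
                                n_samples = 10000L,
                                drive_topology = c("within_network", "global",
                                                   "network_subset"),
                                driven_networks = NULL, seed = 1L) {
  drive_topology <- match.arg(drive_topology)
  stopifnot(is_count(n_networks), is_count(units_per_network),
            w_drive >= 0, w_global >= 0, is_count(n_samples, 2L))
  if (drive_topology == "network_subset") {
    if (is.null(driven_networks) || !all(driven_networks %in% seq_len(n_networks))) {
      stop("network_subset topology requires driven_networks within 1..n_networks")
    }
    driven_networks <- sort(unique(as.integer(driven_networks)))
  } else {
    driven_networks <- seq_len(n_networks)
  }
  structure(list(n_networks = as.integer(n_networks),
                 units_per_network = as.integer(units_per_network),
                 n_units = as.integer(n_networks * units_per_network),
                 w_drive = w_drive, w_global = w_global,
                 n_samples = as.integer(n_samples),
                 drive_topology = drive_topology,
                 driven_networks = driven_networks,
                 seed = as.integer(seed)),
            class = "linear_model_config")
}

lm_membership <- function(config) {
  rep(seq_len(config$n_networks), each = config$units_per_network)
}

#' Simulate the linear network model
#'
#' @param config a [linear_model_config()].
#' @param state `"rest"` (no stimulus drive) or `"task"`.
#' @param seed optional seed overriding `config$seed` (used to pair
#'   independent rest/task runs).
#' @return `n_samples x n_units` matrix of unit activities.
#' @export
simulate_linear_network <- function(config, state = c("rest", "task"),
                                    seed = NULL) {
  stopifnot(inherits(config, "linear_model_config"))
  state <- match.arg(state)
  n <- config$n_samples
  net <- lm_membership(config)
  with_seed(seed %||% derive_seed(config$seed, paste0("linear:", state)), {
    shared <- matrix(stats::rnorm(n * config$n_networks), n, config$n_networks)
    x <- shared[, net] + matrix(stats::rnorm(n * config$n_units), n, config$n_units)
    if (config$w_global > 0) {
      x <- x + config$w_global * stats::rnorm(n)
    }
    if (state == "task" && config$w_drive > 0) {
      if (config$drive_topology == "global") {
        x <- x + config$w_drive * stats::rnorm(n)
      } else {
        drives <- matrix(stats::rnorm(n * config$n_networks), n, config$n_networks)
        driven <- net %in% config$driven_networks
        x[, driven] <- x[, driven] + config$w_drive * drives[, net[driven]]
      }
    }
    colnames(x) <- sprintf("U%03d", seq_len(config$n_units))
    x
  })
}

# Exact population covariance implied by the component structure.
analytic_covariance <- function(config, state) {
  net <- lm_membership(config)
  same_net <- outer(net, net, "==")
  v <- matrix(config$w_global^2, config$n_units, config$n_units)
  v[same_net] <- v[same_net] + 1            # x_shared
  diag(v) <- diag(v) + 1                    # x_private
  if (state == "task" && config$w_drive > 0) {
    if (config$drive_topology == "global") {
      v <- v + config$w_drive^2
    } else {
      driven <- net %in% config$driven_networks
      add <- same_net & outer(driven, driven, "&")
      v[add] <- v[add] + config$w_drive^2
    }
  }
  v
}

#' Closed-form correlations of the linear network model
#'
#' Exact population within- and between-network correlations implied by the
#' component variances: with independent standard-normal components the
#' covariance of two units is the summed squared weight of their shared
#' components, and the variance adds the private component. E.g. at rest the
#' within-network correlation is `(1 + w_global^2) / (2 + w_global^2)`.
#' For heterogeneous topologies (`network_subset`) the mean over the relevant
#' unit pairs of the exact entrywise correlation matrix is returned.
#'
#' @param config a [linear_model_config()].
#' @param state `"rest"` or `"task"`.
#' @return list with `within_network` and `between_network` correlations and
#'   the exact `matrix`.
#' @export
analytic_correlations <- function(config, state = c("rest", "task")) {
  stopifnot(inherits(config, "linear_model_config"))
  state <- match.arg(state)
  v <- analytic_covariance(config, state)
  r <- stats::cov2cor(v)
  net <- lm_membership(config)
  same <- outer(net, net, "==") & row(r) != col(r)
  betw <- !outer(net, net, "==")
  list(within_network = mean(r[same]), between_network = mean(r[betw]),
       matrix = r)
}

#' Task-versus-rest noise-correlation change in the linear model
#'
#' Simulates paired rest and task runs (independent derived sub-seeds, so the
#' difference is not artificially noise-cancelled), and returns the simulated
#' deltaNC matrix together with its analytic counterpart.
#'
#' @param config a [linear_model_config()].
#' @return list with `delta_nc` (simulated task - rest correlation matrix),
#'   `analytic` (list with `within_network`, `between_network`, `matrix`),
#'   and the simulated `rest`/`task` correlation matrices.
#' @export
model_delta_nc <- function(config) {
  stopifnot(inherits(config, "linear_model_config"))
  rest <- stats::cor(simulate_linear_network(
    config, "rest", seed = derive_seed(config$seed, "deltanc:rest")))
  task <- stats::cor(simulate_linear_network(
    config, "task", seed = derive_seed(config$seed, "deltanc:task")))
  ana_r <- analytic_correlations(config, "rest")
  ana_t <- analytic_correlations(config, "task")
  list(delta_nc = task - rest,
       analytic = list(within_network = ana_t$within_network - ana_r$within_network,
                       between_network = ana_t$between_network - ana_r$between_network,
                       matrix = ana_t$matrix - ana_r$matrix),
       rest = rest, task = task)
}
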