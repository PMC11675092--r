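# Orchestration: one call running synthetic generation -> correlations ->
# differential -> network metrics -> cliques -> decoding -> statistics, with
# every artifact written to disk alongside a JSON sidecar carrying the config
# hash, so each number is traceable to the run that produced it.

config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  sprintf("%08x", derive_seed(0L, s))
}

#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically read from JSON with
#' [read_run_config()]) with fields:
#' `seed` (master seed), `outdir` (output directory), `scenario` (arguments
#' for [scenario_spec()], or a path to a scenario JSON), optional `partition`
#' (path to a partition TSV, or an integer number of equal-sized networks to
#' assign round-robin), `stages` (subset of `correlations`, `differential`,
#' `netmetrics`, `cliques`, `decoding`; earlier dependencies are implied),
#' `retain_fraction` (threshold fraction, default 0.2), `clique_k`
#' (default 5), `n_boot` (default 20).
#'
#' @param config named list.
#' @return the completed configuration (defaults filled in).
#' @export
validate_run_config <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config$outdir)) stop("run config needs an 'outdir'")
  if (is.null(config$scenario)) stop("run config needs a 'scenario'")
  config$seed <- config$seed %||% 1L
  config$stages <- config$stages %||% c("correlations", "differential",
                                        "netmetrics", "cliques", "decoding")
  known <- c("correlations", "differential", "netmetrics", "cliques", "decoding")
  bad <- setdiff(config$stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  config$retain_fraction <- config$retain_fraction %||% 0.2
  config$clique_k <- config$clique_k %||% 5L
  config$n_boot <- config$n_boot %||% 20L
  config
}

#' @rdname validate_run_config
#' @param path path to a JSON run configuration.
#' @export
read_run_config <- function(path) {
  validate_run_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

resolve_scenario <- function(config) {
  sc <- config$scenario
  if (is.character(sc)) return(read_scenario_json(sc))
  if (inherits(sc, "scenario_spec")) return(sc)
  sc$seed <- sc$seed %||% config$seed
  if (!is.null(sc$tuning)) sc$tuning <- as.matrix(sc$tuning)
  if (!is.null(sc$sigma_rest)) sc$sigma_rest <- as.matrix(sc$sigma_rest)
  if (!is.null(sc$sigma_task)) {
    sc$sigma_task <- if (is.list(sc$sigma_task)) lapply(sc$sigma_task, as.matrix)
                     else as.matrix(sc$sigma_task)
  }
  do.call(scenario_spec, sc)
}

resolve_partition <- function(config, spec) {
  p <- config$partition
  if (is.null(p)) p <- min(4L, spec$n_regions %/% 2L)
  if (is.character(p) && length(p) == 1L && file.exists(p)) {
    return(read_partition(p))
  }
  if (length(p) == 1L && is.numeric(p)) {
    labels <- sprintf("net%02d", rep_len(seq_len(p), spec$n_regions))
    return(network_partition(spec$region_labels, labels))
  }
  network_partition(spec$region_labels, p)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Executes the requested stages in dependency order, writes every artifact
#' (TSV matrices, JSON summaries) under `config$outdir`, and returns the
#' report bundle. With `resume = TRUE`, stages whose artifacts already exist
#' for the same configuration hash are loaded from disk instead of
#' recomputed; all randomness derives from `config$seed`, so re-running a
#' configuration reproduces bit-identical outputs.
#'
#' @param config run configuration (see [validate_run_config()]).
#' @param resume reuse cached stage outputs when present (default `FALSE`).
#' @return a list of class `report_bundle` with (depending on stages)
#'   `dataset`, `group` (SC/rNC/tNC/deltaNC `corr_matrix` objects),
#'   `differential`, `alignment`, `netmetrics`, `cliques`, `decoding`,
#'   `stats`, plus `config` and `hash`.
#' @export
run_pipeline <- function(config, resume = FALSE) {
  config <- validate_run_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config[setdiff(names(config), "outdir")])
  stamp <- file.path(config$outdir, "run.json")
  prev <- if (file.exists(stamp)) jsonlite::read_json(stamp)$hash else NULL
  cached <- function(f) resume && identical(prev, hash) &&
    file.exists(file.path(config$outdir, f))
  out_path <- function(f) file.path(config$outdir, f)
  side <- list(config_hash = hash,
               package_version = as.character(utils::packageVersion("signoise")))

  spec <- resolve_scenario(config)
  bundle <- list(config = config, hash = hash)

  dataset <- generate_dataset(spec)
  bundle$dataset <- dataset
  for (b in dataset$betas) {
    f <- sprintf("betas_%s.tsv", b$subject)
    if (!cached(f)) write_beta_series(b, out_path(f))
  }

  stages <- config$stages
  need <- function(s) s %in% stages ||
    any(c("differential", "netmetrics", "cliques", "decoding") %in% stages)

  group <- NULL
  if (need("correlations")) {
    scs <- lapply(dataset$betas, compute_sc)
    ncs <- lapply(dataset$betas, compute_nc)
    group <- list(sc = group_average(scs),
                  tnc = group_average(lapply(ncs, `[[`, "tnc")),
                  rnc = group_average(lapply(ncs, `[[`, "rnc")))
    group$dnc <- compute_delta_nc(group$tnc, group$rnc)
    for (nm in names(group)) {
      f <- sprintf("group_%s.tsv", nm)
      if (!cached(f)) write_matrix_tsv(group[[nm]], out_path(f), sidecar = side)
    }
    bundle$group <- group
  }

  partition <- resolve_partition(config, spec)
  if (!cached("partition.tsv")) write_partition(partition, out_path("partition.tsv"))

  diffm <- NULL
  if (any(c("differential", "cliques", "decoding") %in% stages)) {
    diffm <- signal_noise_differential(group$sc, group$dnc)
    if (!cached("differential.tsv")) {
      write_matrix_tsv(diffm$values, out_path("differential.tsv"), sidecar = side)
    }
    bundle$differential <- diffm
    bundle$alignment <- alignment_summary(diffm, partition)
    if (!cached("alignment.json")) {
      jsonlite::write_json(c(bundle$alignment[c("overall", "per_network")], side),
                           out_path("alignment.json"), auto_unbox = TRUE,
                           digits = NA)
    }
  }

  if ("netmetrics" %in% stages) {
    bundle$netmetrics <- list(
      modularity_sc = signed_modularity(group$sc, partition),
      modularity_rnc = signed_modularity(group$rnc, partition),
      segregation_sc = segregation(group$sc, partition),
      segregation_rnc = segregation(group$rnc, partition),
      gradients_sc = principal_gradients(group$sc),
      gradients_rnc = principal_gradients(group$rnc))
    if (!cached("netmetrics.json")) {
      nm <- bundle$netmetrics
      jsonlite::write_json(c(list(
        q_star_sc = nm$modularity_sc$q_star,
        q_star_rnc = nm$modularity_rnc$q_star,
        mean_segregation_sc = nm$segregation_sc$mean_segregation,
        mean_segregation_rnc = nm$segregation_rnc$mean_segregation,
        variance_explained_sc = nm$gradients_sc$variance_explained,
        variance_explained_rnc = nm$gradients_rnc$variance_explained,
        modularity_combine = nm$modularity_sc$combine), side),
        out_path("netmetrics.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  if (any(c("cliques", "decoding") %in% stages)) {
    k <- config$clique_k
    picks <- lapply(c(aligned = "aligned", anti_aligned = "anti_aligned"),
                    function(sgn) {
      tryCatch(strongest_clique(diffm, k = k, sign = sgn,
                                retain_fraction = config$retain_fraction),
               error = function(e) NULL)
    })
    bundle$cliques <- picks
    if (!cached("cliques.json")) {
      jsonlite::write_json(c(lapply(picks, function(cs) {
        if (is.null(cs)) NULL else list(members = cs$cliques[[1]],
                                        strength = cs$strength[1],
                                        sign = cs$sign, k = cs$k,
                                        retain_fraction = cs$retain_fraction)
      }), side), out_path("cliques.json"), auto_unbox = TRUE, digits = NA)
    }
  }

  if ("decoding" %in% stages) {
    rows <- list()
    for (sgn in names(bundle$cliques)) {
      cs <- bundle$cliques[[sgn]]
      if (is.null(cs)) next
      regions <- cs$cliques[[1]]
      for (s in seq_along(dataset$betas)) {
        for (cond in c(FALSE, TRUE)) {
          dr <- decode_multitask(
            dataset$betas[[s]], regions, shuffle_training = cond,
            seed = derive_seed(config$seed, sprintf("decode:%s:%d", sgn, s)),
            n_boot = config$n_boot)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = dr$subject, region_set = sgn, condition = dr$condition,
            accuracy = dr$accuracy, stringsAsFactors = FALSE)
        }
      }
    }
    if (!length(rows)) {
      warning("decoding stage skipped: no clique of either sign was found")
    }
    decoding <- do.call(rbind, rows)
    bundle$decoding <- decoding
    if (!cached("decoding.tsv") && length(rows)) {
      write_tsv_full(decoding, out_path("decoding.tsv"))
    }
    if (length(rows) && length(dataset$betas) >= 6 &&
        all(c("aligned", "anti_aligned") %in% decoding$region_set)) {
      acc <- function(set, cond) {
        decoding$accuracy[decoding$region_set == set & decoding$condition == cond]
      }
      bundle$stats <- list(
        anti_vs_aligned = compare_conditions(acc("anti_aligned", "unshuffled"),
                                             acc("aligned", "unshuffled")),
        shuffle_effect_anti = compare_conditions(acc("anti_aligned", "unshuffled"),
                                                 acc("anti_aligned", "shuffled")),
        shuffle_effect_aligned = compare_conditions(acc("aligned", "unshuffled"),
                                                    acc("aligned", "shuffled")))
      if (!cached("stats.json")) {
        jsonlite::write_json(c(bundle$stats, side), out_path("stats.json"),
                             auto_unbox = TRUE, digits = NA)
      }
    }
  }

  jsonlite::write_json(c(list(hash = hash), side["package_version"],
                         list(stages = stages)),
                       stamp, auto_unbox = TRUE, digits = NA)
  class(bundle) <- "report_bundle"
  bundle
}

#' @export
print.report_bundle <- function(x, ...) {
  cat(sprintf("report_bundle [%s]: stages %s, %d subjects\n", x$hash,
              paste(x$config$stages, collapse = ", "),
              length(x$dataset$betas)))
  invisible(x)
}
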