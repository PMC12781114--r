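#' Default demo run configuration
#'
#' A complete, valid configuration that simulates a closed-dominant
#' (wild-type-like) and an open-dominant (mutant-like) gate ensemble,
#' runs the structural stages (trim, PCA, contacts, dCNA, gate distances)
#' and the kinetic fits on simulated datasets.
#'
#' @param output_dir where artifacts are written.
#' @param seed RNG seed for every stochastic stage.
#' @return a nested list understood by [run_pipeline()].
#' @export
default_run_config <- function(output_dir = tempfile("nqogate_run_"),
                               seed = 1L) {
  list(
    seed = as.integer(seed),
    output_dir = output_dir,
    structural = list(
      enabled = TRUE,
      systems = list(
        wt = list(generator = list(closed_mean_distance = 11.6,
                                   open_mean_distance = 21.0,
                                   fluctuation_sd = 1.4,
                                   p_closed_to_open = 0.01,
                                   p_open_to_closed = 0.2,
                                   n_frames = 400L, start_state = "closed")),
        mutant = list(generator = list(closed_mean_distance = 11.6,
                                       open_mean_distance = 21.0,
                                       fluctuation_sd = 2.9,
                                       p_closed_to_open = 0.2,
                                       p_open_to_closed = 0.01,
                                       n_frames = 400L,
                                       start_state = "open"))
      ),
      equilibration_fraction = 0.8,
      selection = "name CA",
      gate_atoms = c("resid 10 and name CA", "resid 30 and name CA"),
      contact_cutoff = 4.5,
      min_separation = 3L,
      stable_threshold = 0.7,
      df_threshold = 0.5,
      n_blocks = 4L,
      pca_components = 2L
    ),
    kinetics = list(
      enabled = TRUE,
      generator = list(),
      trace_concentrations = c(90, 150, 250, 350, 500)
    )
  )
}

#' Validate a run configuration
#'
#' Exhaustive, non-throwing validation; every problem becomes one finding.
#'
#' @param config a configuration list (see [default_run_config()]) or the
#'   path of a YAML file holding one.
#' @return data.frame with columns `field` and `message`; zero rows when
#'   the configuration is valid.
#' @export
validate_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      return(data.frame(field = "config", message = paste("file not found:",
                                                          config)))
    config <- yaml::read_yaml(config)
  }
  finding <- function(field, message) data.frame(field = field,
                                                 message = message,
                                                 stringsAsFactors = FALSE)
  out <- list()
  add <- function(f) out[[length(out) + 1L]] <<- f
  if (is.null(config$output_dir)) add(finding("output_dir", "missing"))
  if (is.null(config$seed) || !is.numeric(config$seed))
    add(finding("seed", "missing or non-numeric"))
  st <- config$structural
  if (isTRUE(st$enabled)) {
    if (length(st$systems) < 1L)
      add(finding("structural.systems", "at least one system required"))
    for (nm in names(st$systems)) {
      sys <- st$systems[[nm]]
      if (is.null(sys$generator)) {
        for (p in c("topology", "trajectory")) {
          if (is.null(sys[[p]]))
            add(finding(paste0("structural.systems.", nm, ".", p),
                        "missing (neither generator nor file inputs given)"))
          else if (!file.exists(sys[[p]]))
            add(finding(paste0("structural.systems.", nm, ".", p),
                        paste("file not found:", sys[[p]])))
        }
      } else {
        ok <- tryCatch({
          do.call(ensemble_spec, sys$generator)
          TRUE
        }, error = function(e) conditionMessage(e))
        if (!isTRUE(ok))
          add(finding(paste0("structural.systems.", nm, ".generator"), ok))
      }
    }
    num_checks <- list(
      c("equilibration_fraction", 0, 1),
      c("contact_cutoff", 0, Inf),
      c("stable_threshold", 0, 1),
      c("df_threshold", 0, Inf))
    for (ck in num_checks) {
      v <- st[[ck[1]]]
      if (!is.null(v) && (!is.numeric(v) || v <= as.numeric(ck[2]) ||
                          v > as.numeric(ck[3])))
        add(finding(paste0("structural.", ck[1]),
                    paste0("must lie in (", ck[2], ", ", ck[3], "]")))
    }
    if (!is.null(st$min_separation) && st$min_separation < 0)
      add(finding("structural.min_separation", "must be >= 0"))
  }
  kin <- config$kinetics
  if (isTRUE(kin$enabled)) {
    if (!is.null(kin$rates_csv) && !file.exists(kin$rates_csv))
      add(finding("kinetics.rates_csv", paste("file not found:",
                                              kin$rates_csv)))
    if (is.null(kin$rates_csv) && is.null(kin$generator))
      add(finding("kinetics.generator",
                  "missing (no rates_csv and no generator)"))
    if (!is.null(kin$generator)) {
      ok <- tryCatch({
        do.call(kinetics_sim_spec, kin$generator)
        TRUE
      }, error = function(e) conditionMessage(e))
      if (!isTRUE(ok)) add(finding("kinetics.generator", ok))
    }
  }
  if (!length(out))
    data.frame(field = character(0), message = character(0),
               stringsAsFactors = FALSE)
  else do.call(rbind, out)
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(config, tf, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tf))
}

#' Run the full gating / kinetics analysis pipeline
#'
#' Executes the configured stages in dependency order: simulate or ingest
#' the structural systems, trim equilibration, superpose, pooled PCA with
#' densities, contact probabilities, difference contact network with
#' consensus communities, gate distances; then the kinetic fits. A stage
#' failure aborts only its downstream dependents; every artifact lands
#' under `output_dir`. With a fixed seed the run is deterministic.
#'
#' @param config configuration list or YAML path (see
#'   [default_run_config()], [validate_run_config()]).
#' @return a `RunReport`: `stages` data.frame (stage, status, message),
#'   `artifacts` (named paths), `parameters`, `version`, `config_hash`,
#'   `seed`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  findings <- validate_run_config(config)
  if (nrow(findings))
    stop("invalid configuration:\n",
         paste0("  ", findings$field, ": ", findings$message,
                collapse = "\n"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  stages <- list()
  artifacts <- list()
  note <- function(stage, status, message = "") stages[[stage]] <<-
    data.frame(stage = stage, status = status, message = message,
               stringsAsFactors = FALSE)
  run_stage <- function(stage, deps, fun) {
    failed_dep <- deps[vapply(deps, function(d)
      !identical(stages[[d]]$status, "ok"), logical(1))]
    if (length(failed_dep)) {
      note(stage, "skipped", paste("dependency failed:",
                                   paste(failed_dep, collapse = ", ")))
      return(invisible(NULL))
    }
    tryCatch({
      fun()
      note(stage, "ok")
    }, error = function(e) note(stage, "error", conditionMessage(e)))
  }
  env <- new.env()
  st <- config$structural
  if (isTRUE(st$enabled)) {
    run_stage("simulate_structural", character(0), function() {
      env$systems <- list()
      i <- 0L
      for (nm in names(st$systems)) {
        i <- i + 1L
        sys <- st$systems[[nm]]
        if (!is.null(sys$generator)) {
          args <- sys$generator
          if (is.null(args$rng_seed)) args$rng_seed <- config$seed + i
          ens <- simulate_gate_ensemble(do.call(ensemble_spec, args))
          env$systems[[nm]] <- list(topology = ens$structure,
                                    trajectory = ens$trajectory)
          write_structure(ens$structure, out(paste0(nm, "_topology.pdb")))
          write_trajectory(ens$trajectory, out(paste0(nm, "_traj.dcd")))
          artifacts[[paste0(nm, "_topology")]] <<-
            out(paste0(nm, "_topology.pdb"))
          artifacts[[paste0(nm, "_trajectory")]] <<-
            out(paste0(nm, "_traj.dcd"))
        } else {
          topo <- read_structure(sys$topology)
          env$systems[[nm]] <-
            list(topology = topo,
                 trajectory = read_trajectory(sys$trajectory, topo))
        }
      }
    })
    run_stage("trim", "simulate_structural", function() {
      frac <- st$equilibration_fraction
      if (is.null(frac)) frac <- 1
      for (nm in names(env$systems))
        env$systems[[nm]]$trajectory <-
          trim_equilibration(env$systems[[nm]]$trajectory, frac)
    })
    run_stage("pca", "trim", function() {
      top <- env$systems[[1]]$topology
      sel <- select_atoms(top, st$selection)
      trajs <- lapply(env$systems, `[[`, "trajectory")
      model <- fit_pca(trajs, sel)
      env$pca <- model
      ncomp <- if (is.null(st$pca_components)) 2L else st$pca_components
      projs <- lapply(names(trajs), function(nm)
        project(trajs[[nm]], model, ncomp, system_label = nm))
      names(projs) <- names(trajs)
      env$projections <- projs
      sc <- data.frame(component = seq_along(model$eigenvalues),
                       eigenvalue_A2 = model$eigenvalues,
                       cumulative_variance = scree(model))
      utils::write.csv(sc, out("scree.csv"), row.names = FALSE)
      artifacts$scree <<- out("scree.csv")
      proj_df <- do.call(rbind, lapply(projs, function(p)
        data.frame(system = p$system_label, frame = seq_len(nrow(p$scores)),
                   p$scores)))
      utils::write.csv(proj_df, out("projections.csv"), row.names = FALSE)
      artifacts$projections <<- out("projections.csv")
      dens <- density2d(projs)
      env$densities <- dens
      dd <- do.call(rbind, lapply(dens, function(dm) {
        g <- expand.grid(pc1 = dm$x, pc2 = dm$y)
        data.frame(system = dm$system_label, g,
                   density = as.vector(dm$density))
      }))
      utils::write.csv(dd, out("pc_density.csv"), row.names = FALSE)
      artifacts$pc_density <<- out("pc_density.csv")
      mp <- vapply(names(projs), function(nm)
        most_probable_frame(projs[[nm]], dens[[nm]]), integer(1))
      jsonlite::write_json(as.list(mp), out("most_probable_frames.json"),
                           auto_unbox = TRUE)
      artifacts$most_probable_frames <<- out("most_probable_frames.json")
    })
    run_stage("contacts", "trim", function() {
      cutoff <- if (is.null(st$contact_cutoff)) 4.5 else st$contact_cutoff
      msep <- if (is.null(st$min_separation)) 3L else st$min_separation
      env$contact_probs <- lapply(env$systems, function(s)
        contact_probabilities(s$trajectory, cutoff, msep))
      for (nm in names(env$contact_probs)) {
        utils::write.csv(env$contact_probs[[nm]]$values,
                         out(paste0(nm, "_contact_probability.csv")))
        artifacts[[paste0(nm, "_contact_probability")]] <<-
          out(paste0(nm, "_contact_probability.csv"))
      }
    })
    run_stage("dcna", "contacts", function() {
      nms <- names(env$systems)
      if (length(nms) < 2L) stop("dCNA needs two systems")
      cutoff <- if (is.null(st$contact_cutoff)) 4.5 else st$contact_cutoff
      msep <- if (is.null(st$min_separation)) 3L else st$min_separation
      diffnet <- difference_network(env$contact_probs[[nms[1]]],
                                    env$contact_probs[[nms[2]]],
                                    labels = nms[1:2])
      utils::write.csv(diffnet$df, out("df_matrix.csv"))
      artifacts$df_matrix <<- out("df_matrix.csv")
      thr <- if (is.null(st$df_threshold)) 0.5 else st$df_threshold
      utils::write.csv(significant_edges(diffnet, thr), out("df_edges.csv"),
                       row.names = FALSE)
      artifacts$df_edges <<- out("df_edges.csv")
      nb <- if (is.null(st$n_blocks)) 4L else st$n_blocks
      blocks <- list()
      for (nm in nms[1:2]) {
        tr <- env$systems[[nm]]$trajectory
        nf <- n_frames(tr)
        cuts <- floor(seq(0, nf, length.out = nb + 1L))
        for (b in seq_len(nb)) {
          blk <- Trajectory(tr$topology,
                            tr$xyz[(cuts[b] + 1L):cuts[b + 1L], ,
                                   drop = FALSE])
          blocks[[length(blocks) + 1L]] <-
            contact_probabilities(blk, cutoff, msep)
        }
      }
      sthr <- if (is.null(st$stable_threshold)) 0.7 else st$stable_threshold
      part <- consensus_communities(blocks, sthr)
      env$partition <- part
      utils::write.csv(data.frame(residue = names(part$labels),
                                  community = as.integer(part$labels),
                                  stability = as.numeric(part$stability)),
                       out("communities.csv"), row.names = FALSE)
      artifacts$communities <<- out("communities.csv")
      cd <- community_difference(diffnet, part)
      utils::write.csv(cd$net_df, out("community_net_df.csv"))
      artifacts$community_net_df <<- out("community_net_df.csv")
    })
    run_stage("distances", "trim", function() {
      ga <- st$gate_atoms
      if (is.null(ga) || length(ga) != 2L)
        stop("structural.gate_atoms must give two selections")
      res <- lapply(names(env$systems), function(nm) {
        ser <- distance_series(env$systems[[nm]]$trajectory, ga[1], ga[2],
                               system_label = nm)
        utils::write.csv(data.frame(frame = seq_along(ser$values),
                                    distance_A = ser$values),
                         out(paste0(nm, "_gate_distance.csv")),
                         row.names = FALSE)
        artifacts[[paste0(nm, "_gate_distance")]] <<-
          out(paste0(nm, "_gate_distance.csv"))
        gs <- gate_stats(ser)
        list(mean_A = gs$mean, sd_A = gs$sd, n_frames = gs$n_frames)
      })
      names(res) <- names(env$systems)
      jsonlite::write_json(res, out("gate_stats.json"), auto_unbox = TRUE,
                           digits = NA)
      artifacts$gate_stats <<- out("gate_stats.json")
    })
  } else {
    for (s in c("simulate_structural", "trim", "pca", "contacts", "dcna",
                "distances"))
      note(s, "skipped", "structural stages disabled")
  }
  kin <- config$kinetics
  if (isTRUE(kin$enabled)) {
    run_stage("kinetics_data", character(0), function() {
      if (!is.null(kin$rates_csv)) {
        env$rates <- read_rates_csv(kin$rates_csv)
        env$kin_spec <- NULL
      } else {
        args <- kin$generator
        if (is.null(args$rng_seed)) args$rng_seed <- config$seed + 100L
        env$kin_spec <- do.call(kinetics_sim_spec, args)
        env$rates <- simulate_rates(env$kin_spec)
        write_rates_csv(env$rates, out("rates.csv"))
        artifacts$rates <<- out("rates.csv")
      }
    })
    run_stage("fit_steadystate", "kinetics_data", function() {
      f1 <- fit_pingpong(env$rates)
      f2 <- fit_pingpong_substrate_inhibition(env$rates)
      sel <- select_model(f1, f2)
      best <- if (sel$choice == "eq1") f1 else f2
      res <- list(model = sel$choice,
                  aicc = as.list(sel$aicc),
                  f_test = list(statistic = sel$f_statistic,
                                p_value = sel$p_value),
                  kcat = best$kcat, K_NADH = best$Ka, K_CoQ0 = best$Kb,
                  K_is = if (sel$choice == "eq2") best$Kis else NULL,
                  se = as.list(best$se), r_squared = best$r_squared)
      eff <- efficiency(best$kcat, best$Kb, best$se[["kcat"]],
                        best$se[["Kb"]])
      res$kcat_over_K_CoQ0 <- eff$value
      res$kcat_over_K_CoQ0_se <- eff$se
      jsonlite::write_json(res, out("steadystate_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts$steadystate_fit <<- out("steadystate_fit.json")
    })
    run_stage("fit_transient", "kinetics_data", function() {
      conc <- kin$trace_concentrations
      if (is.null(conc)) stop("kinetics.trace_concentrations missing")
      if (is.null(env$kin_spec))
        stop("transient stage currently requires the generator")
      traces <- simulate_traces(env$kin_spec, conc)
      per_trace <- lapply(traces, fit_biexponential)
      sat <- fit_saturation(data.frame(
        S = conc, kobs = vapply(per_trace, `[[`, numeric(1), "kobs1")))
      res <- list(
        per_trace = lapply(seq_along(conc), function(i)
          list(NADH_uM = conc[i], kobs1 = per_trace[[i]]$kobs1,
               kobs2 = per_trace[[i]]$kobs2,
               amplitude_fraction_fast =
                 per_trace[[i]]$amplitude_fraction_fast)),
        kred = sat$kred, Kd = sat$Kd, se = as.list(sat$se),
        r_squared = sat$r_squared)
      jsonlite::write_json(res, out("transient_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      artifacts$transient_fit <<- out("transient_fit.json")
    })
  } else {
    for (s in c("kinetics_data", "fit_steadystate", "fit_transient"))
      note(s, "skipped", "kinetics stages disabled")
  }
  report <- structure(list(
    stages = do.call(rbind, stages),
    artifacts = artifacts,
    parameters = config,
    version = as.character(utils::packageVersion("nqogate")),
    config_hash = config_hash(config),
    seed = config$seed), class = "RunReport")
  jsonlite::write_json(list(stages = report$stages,
                            artifacts = artifacts,
                            version = report$version,
                            config_hash = report$config_hash,
                            seed = report$seed),
                       out("run_report.json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  report
}

#' @export
print.RunReport <- function(x, ...) {
  cat("RunReport (nqogate", x$version, ", config", substr(x$config_hash, 1,
                                                          8), ")\n")
  for (i in seq_len(nrow(x$stages)))
    cat(sprintf("  %-20s %-8s %s\n", x$stages$stage[i], x$stages$status[i],
                x$stages$message[i]))
  invisible(x)
}
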