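# Umbrella pipeline: synthetic course -> transporter fit -> pathway
# thermodynamics / enzyme cost (when parameters are available) -> dFBA ->
# condition scans, with a reproducibility manifest.

#' Run the modeling pipeline end to end
#'
#' Executes the requested stages in dependency order and writes each result
#' plus a JSON manifest (stage list, seeds, input hashes, package version)
#' to `out_dir`. Stage failures halt downstream stages; the manifest
#' records the partial state.
#'
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("synth", "fit", "thermo", "dfba", "scan")`.
#' @param batch_spec [synthetic_batch_spec()] for the synthetic course.
#' @param pathway_params optional path to a parameter table merged onto the
#'   shipped pathways for the thermo stage (without it the thermo stage
#'   reports the parameter checklist and the stoichiometric yields only).
#' @param seed integer seed governing fit restarts and cost optimization.
#' @param n_restarts transporter-fit restarts.
#' @param kla_values,ratios scan grids.
#' @param dt,t_end dFBA step and horizon, h.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(out_dir, stages = c("synth", "fit", "thermo",
                                             "dfba", "scan"),
                         batch_spec = synthetic_batch_spec(),
                         pathway_params = NULL, seed = 1L,
                         n_restarts = 5L,
                         kla_values = c(10, 30, 60, 120),
                         ratios = c(0.5, 1, 2, 4),
                         dt = 0.2, t_end = 65) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "zymoflux",
                   version = as.character(utils::packageVersion("zymoflux")),
                   seed = seed, stages = list())
  mark <- function(stage, status, outputs = character()) {
    manifest$stages[[stage]] <<- list(status = status, outputs = outputs)
  }
  synth <- fit <- NULL
  run_stage <- function(stage, fun) {
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      mark(stage, paste("failed:", conditionMessage(res)))
      NULL
    } else res
  }
  if ("synth" %in% stages) {
    synth <- run_stage("synth", function() {
      s <- generate_fermentation(batch_spec)
      p <- file.path(out_dir, "course.tsv")
      write_course_tsv(s$course, p)
      mark("synth", "ok", p)
      s
    })
  }
  if ("fit" %in% stages && !is.null(synth)) {
    fit <- run_stage("fit", function() {
      f <- fit_transporter(synth$course, n_restarts = n_restarts, seed = seed)
      p <- file.path(out_dir, "fit.json")
      write_fit_json(f, p)
      mark("fit", "ok", p)
      f
    })
  }
  if ("thermo" %in% stages) {
    run_stage("thermo", function() {
      glc_pw <- glucose_bdo_pathway()
      xyl_pw <- xylose_bdo_pathway()
      if (!is.null(pathway_params)) {
        tab <- load_parameter_table(pathway_params)
        glc_pw <- merge_parameters(glc_pw, tab)
        xyl_pw <- merge_parameters(xyl_pw, tab)
      }
      yields <- list(glucose = as.list(net_yields(glc_pw)),
                     xylose = as.list(net_yields(xyl_pw)))
      p <- file.path(out_dir, "yields.json")
      jsonlite::write_json(yields, p, auto_unbox = TRUE, digits = NA)
      outs <- p
      ready <- function(pw) nrow(attr(pw, "missing") %||% data.frame()) == 0 &&
        !anyNA(vapply(pw$reactions, `[[`, numeric(1), "dg0_prime"))
      if (!is.null(pathway_params) && ready(glc_pw) && ready(xyl_pw)) {
        res <- lapply(list(glucose = glc_pw, xylose = xyl_pw), function(pw) {
          m <- optimize_mdf(pw)
          ec <- minimize_pathway_cost(pw, seed = seed, mdf_sol = m)
          list(mdf = m$mdf, total_dg = m$total_dg,
               total_cost = ec$total_cost,
               bottlenecks = bottleneck_report(pw))
        })
        p2 <- file.path(out_dir, "thermo.json")
        jsonlite::write_json(res, p2, auto_unbox = TRUE, digits = NA)
        outs <- c(outs, p2)
      }
      mark("thermo", "ok", outs)
      TRUE
    })
  }
  tk <- if (!is.null(fit)) fit$params else batch_spec$true_params
  net <- zm_core_network()
  traj <- NULL
  if ("dfba" %in% stages) {
    traj <- run_stage("dfba", function() {
      tr <- simulate_batch(net, tk, t_end = t_end, dt = dt)
      p <- file.path(out_dir, "trajectory.tsv")
      write_trajectory_tsv(tr, p)
      mark("dfba", "ok", p)
      tr
    })
  }
  if ("scan" %in% stages && !is.null(traj)) {
    run_stage("scan", function() {
      rs <- sugar_ratio_scan(ratios, net = net, tk = tk, t_end = t_end, dt = dt)
      ks <- kla_scan(kla_values, net = net, tk = tk, t_end = t_end, dt = dt)
      p1 <- file.path(out_dir, "ratio_scan.tsv")
      p2 <- file.path(out_dir, "kla_scan.tsv")
      utils::write.table(rs$summary, p1, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      utils::write.table(ks$summary, p2, sep = "\t", row.names = FALSE,
                         quote = FALSE)
      mark("scan", "ok", c(p1, p2))
      TRUE
    })
  }
  files <- unlist(lapply(manifest$stages, `[[`, "outputs"))
  manifest$md5 <- as.list(tools::md5sum(files[file.exists(files)]))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
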