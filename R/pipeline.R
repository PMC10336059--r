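#' Default pipeline configuration
#'
#' Study-condition defaults for the end-to-end synthetic pipeline: a
#' 500 x 500 px arena with a lateral refuge, 1 cm = 16.7 px calibration,
#' 1-h exploration/sociability tests and a 2-h activity test at 1 Hz, four
#' trials per individual, and the standard MCMC settings (13,000/3,000/10
#' univariate; 100,000/10,000/100 bivariate).
#'
#' @return a nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    n_individuals = 30L,
    n_trials = 4L,
    prop_wild = 0.5,
    length_mean = 10, length_sd = 1,
    arena = list(width_px = 500, height_px = 500,
                 refuge = c(0, 200, 60, 300),
                 object_point = c(250, 480),
                 conspecific_point = c(490, 250),
                 px_per_cm = 16.7),
    movement = list(step_mean_px = 20, turn_mu_rad = 0, turn_kappa = 1,
                    p_enter_refuge = 0.02, p_exit_refuge = 0.05,
                    durations = list(exploration = 3600L, sociability = 3600L,
                                     activity = 7200L),
                    # individual heterogeneity (log-normal multipliers) that
                    # makes simulated behavior repeatable across trials
                    ind_sd_log_step = 0.4, ind_sd_log_exit = 0.6),
    manual_metrics = list(
      # aggressiveness approach counts: log-normal rate, Poisson counts
      approach_log_mean = 3.0, approach_sd_ind = 0.8, approach_sd_res = 0.3,
      # boldness latencies (s): shared individual boldness factor
      latency_log_mean = 5.5, latency_sd_ind = 0.6, latency_sd_res = 0.25,
      latency_cap_s = 3600),
    mcmc = list(univariate = list(n_iter = 13000L, burn_in = 3000L,
                                  thin = 10L),
                bivariate = list(n_iter = 100000L, burn_in = 10000L,
                                 thin = 100L)),
    fixed_terms = c("trial_c", "length_c", "sample"),
    reduce = FALSE,
    syndrome_pairs = list(c("exploration", "activity"),
                          c("exploration", "sociability")),
    report = list(digits = 2)),
    class = "pipeline_config")
}

#' Load a pipeline configuration
#'
#' Reads a YAML file and merges it over [default_pipeline_config()]; keys
#' not present in the file keep their defaults.
#'
#' @param path YAML config path, or `NULL` for pure defaults.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(path = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
  }
  if (cfg$n_individuals < 2) stop("n_individuals must be >= 2")
  if (cfg$n_trials < 2) stop("n_trials must be >= 2 for repeatability")
  class(cfg) <- "pipeline_config"
  cfg
}

modify_list_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(base[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k * 104729) %% 2147483647L)
}

pipe_log <- function(out_dir, stage, msg) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"),
                  stage, msg)
  message(line)
  cat(line, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
}

manifest_add <- function(out_dir, stage, seed, inputs, outputs) {
  mpath <- file.path(out_dir, "manifest.json")
  man <- if (file.exists(mpath)) jsonlite::read_json(mpath) else list()
  hash <- function(fs) {
    fs <- fs[file.exists(fs)]
    as.list(tools::md5sum(fs))
  }
  man[[stage]] <- list(stage = stage, seed = seed,
                       time = format(Sys.time()),
                       input_md5 = hash(inputs), output_md5 = hash(outputs))
  jsonlite::write_json(man, mpath, auto_unbox = TRUE, pretty = TRUE)
}

arena_from_config <- function(cfg) {
  a <- cfg$arena
  arena_config(a$width_px, a$height_px, unlist(a$refuge),
               object_point = unlist(a$object_point),
               conspecific_point = unlist(a$conspecific_point),
               px_per_cm = a$px_per_cm)
}

#' Run the behavioral-type pipeline
#'
#' Orchestrates simulate -> metrics -> score -> fit -> syndromes -> report
#' on synthetic data with known ground truth. Every stage writes CSV
#' outputs into `out_dir`, appends to `pipeline.log`, and records itself in
#' `manifest.json` (stage, derived seed, input/output MD5 hashes), so a
#' rerun with the same config and seed is byte-reproducible. Stages can be
#' run individually provided their inputs exist in `out_dir`.
#'
#' @param config a [pipeline_config()] (or path to a YAML config).
#' @param out_dir output directory (created if missing).
#' @param seed master integer seed; each stage derives its own sub-seed.
#' @param stages character vector of stages to run, in order.
#' @return `out_dir`, invisibly.
#' @export
run_pipeline <- function(config = default_pipeline_config(),
                         out_dir, seed = 1L,
                         stages = c("simulate", "metrics", "score", "fit",
                                    "syndromes", "report")) {
  if (is.character(config)) config <- pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  known <- c("simulate", "metrics", "score", "fit", "syndromes", "report")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (stage in known[known %in% stages]) {
    t0 <- Sys.time()
    pipe_log(out_dir, stage, "start")
    res <- tryCatch(
      switch(stage,
             simulate = stage_simulate(config, out_dir, derive_seed(seed, 1)),
             metrics = stage_metrics(config, out_dir, derive_seed(seed, 2)),
             score = stage_score(config, out_dir, derive_seed(seed, 3)),
             fit = stage_fit(config, out_dir, derive_seed(seed, 4)),
             syndromes = stage_syndromes(config, out_dir,
                                         derive_seed(seed, 5)),
             report = stage_report(config, out_dir, derive_seed(seed, 6))),
      error = function(e) stop("pipeline stage '", stage, "' failed: ",
                               conditionMessage(e), call. = FALSE))
    pipe_log(out_dir, stage,
             sprintf("done in %.1f s", as.numeric(Sys.time() - t0, "secs")))
  }
  invisible(out_dir)
}

stage_simulate <- function(cfg, out_dir, seed) {
  set.seed(seed)
  n <- cfg$n_individuals
  n_wild <- round(n * cfg$prop_wild)
  ind <- data.frame(id = sprintf("SA%03d", seq_len(n)),
                    sample = rep(c("wild", "reared"), c(n_wild, n - n_wild)),
                    length_cm = rnorm(n, cfg$length_mean, cfg$length_sd))
  mv <- cfg$movement
  # repeatable individual movement styles
  ind$step_mult <- exp(rnorm(n, 0, mv$ind_sd_log_step))
  ind$exit_mult <- exp(rnorm(n, 0, mv$ind_sd_log_exit))
  arena <- arena_from_config(cfg)

  tracks <- list()
  ti <- 0L
  for (i in seq_len(n)) {
    for (trial in seq_len(cfg$n_trials)) {
      for (test in names(mv$durations)) {
        ti <- ti + 1L
        m <- movement_config(
          step_mean_px = mv$step_mean_px * ind$step_mult[i],
          turn_mu_rad = mv$turn_mu_rad, turn_kappa = mv$turn_kappa,
          p_enter_refuge = mv$p_enter_refuge,
          p_exit_refuge = min(1, mv$p_exit_refuge * ind$exit_mult[i]),
          duration_s = mv$durations[[test]])
        tracks[[ti]] <- simulate_trajectory(
          arena, m, seed = derive_seed(seed, 100 + ti),
          id = ind$id[i], trial = trial, test = test)
      }
    }
  }

  # manually-annotated metrics of the real protocol (approach counts,
  # latencies) generated as synthetic values with individual heterogeneity
  mm <- cfg$manual_metrics
  set.seed(derive_seed(seed, 7))
  agg_ind <- rnorm(n, 0, mm$approach_sd_ind)
  bold_ind <- rnorm(n, 0, mm$latency_sd_ind)
  aux <- list()
  for (i in seq_len(n)) {
    for (trial in seq_len(cfg$n_trials)) {
      rate <- exp(mm$approach_log_mean + agg_ind[i] +
                    rnorm(1, 0, mm$approach_sd_res))
      aux[[length(aux) + 1L]] <- data.frame(
        id = ind$id[i], trial = trial, test = "aggressiveness",
        metric = "approaches", value = rpois(1, rate))
      # novel-object approaches share the individual's exploratory tendency
      # (exit_mult), so the exploration metrics covary as one axis
      expl_rate <- exp(1.5 + 1.2 * log(ind$exit_mult[i]) +
                         rnorm(1, 0, mm$approach_sd_res))
      aux[[length(aux) + 1L]] <- data.frame(
        id = ind$id[i], trial = trial, test = "exploration",
        metric = "approaches", value = rpois(1, expl_rate))
      lat <- pmin(mm$latency_cap_s,
                  exp(mm$latency_log_mean + bold_ind[i] +
                        rnorm(3, 0, mm$latency_sd_res)) * c(0.8, 1, 1.3))
      aux[[length(aux) + 1L]] <- data.frame(
        id = ind$id[i], trial = trial, test = "boldness",
        metric = c("head_latency_s", "body_latency_s", "bite_latency_s"),
        value = lat)
    }
  }

  traj_path <- file.path(out_dir, "trajectories.csv")
  ind_path <- file.path(out_dir, "individuals.csv")
  aux_path <- file.path(out_dir, "aux_metrics.csv")
  arena_path <- file.path(out_dir, "arena.yaml")
  write_tracks_csv(tracks, traj_path)
  write.csv(ind[c("id", "sample", "length_cm")], ind_path, row.names = FALSE)
  write.csv(do.call(rbind, aux), aux_path, row.names = FALSE)
  yaml::write_yaml(cfg$arena, arena_path)
  manifest_add(out_dir, "simulate", seed, character(0),
               c(traj_path, ind_path, aux_path, arena_path))
}

stage_metrics <- function(cfg, out_dir, seed) {
  traj_path <- file.path(out_dir, "trajectories.csv")
  aux_path <- file.path(out_dir, "aux_metrics.csv")
  if (!file.exists(traj_path)) stop("missing input: ", traj_path)
  durations <- unlist(cfg$movement$durations)
  tracks <- read_tracks_csv(traj_path, durations = durations)
  if (!length(tracks)) stop("empty trajectory file: ", traj_path)
  arena <- arena_from_config(cfg)
  met <- metrics_long(tracks, arena)
  if (file.exists(aux_path)) met <- rbind(met, read.csv(aux_path))
  met <- met[order(met$id, met$trial, met$test, met$metric), ]
  met_path <- file.path(out_dir, "metrics.csv")
  write.csv(met, met_path, row.names = FALSE)
  # cm-converted companion for length/area metrics
  cm <- met
  px1 <- c("min_distance_px", "total_distance_px")
  px2 <- c("area95_px2", "area50_px2")
  s <- cfg$arena$px_per_cm
  cm$value[cm$metric %in% px1] <- px_to_cm(cm$value[cm$metric %in% px1], s)
  cm$value[cm$metric %in% px2] <- cm$value[cm$metric %in% px2] / s^2
  cm$metric <- sub("_px2$", "_cm2", sub("_px$", "_cm", cm$metric))
  cm$value <- round(cm$value, 2)
  cm_path <- file.path(out_dir, "metrics_cm.csv")
  write.csv(cm, cm_path, row.names = FALSE)
  manifest_add(out_dir, "metrics", seed, c(traj_path, aux_path),
               c(met_path, cm_path))
}

stage_score <- function(cfg, out_dir, seed) {
  met_path <- file.path(out_dir, "metrics.csv")
  ind_path <- file.path(out_dir, "individuals.csv")
  for (p in c(met_path, ind_path))
    if (!file.exists(p)) stop("missing input: ", p)
  met <- read.csv(met_path)
  ind <- read.csv(ind_path)
  axes <- intersect(c("exploration", "sociability", "boldness", "activity"),
                    unique(met$test))
  sc <- score_axes(met, axes = axes)
  scores <- merge(sc$scores, ind, by = "id", sort = TRUE)
  scores <- scores[order(scores$axis, scores$id, scores$trial),
                   c("id", "trial", "sample", "length_cm", "axis", "score")]
  sc_path <- file.path(out_dir, "scores.csv")
  write.csv(scores, sc_path, row.names = FALSE)
  loads <- do.call(rbind, lapply(names(sc$pca), function(ax) {
    data.frame(axis = ax,
               metric = names(sc$pca[[ax]]$loadings),
               loading = as.numeric(sc$pca[[ax]]$loadings),
               variance_fraction = sc$pca[[ax]]$variance_fraction)
  }))
  ld_path <- file.path(out_dir, "loadings.csv")
  write.csv(loads, ld_path, row.names = FALSE)
  manifest_add(out_dir, "score", seed, c(met_path, ind_path),
               c(sc_path, ld_path))
}

score_wide_for_axis <- function(scores, axis) {
  d <- scores[scores$axis == axis, ]
  d$trial_c <- d$trial - mean(d$trial)
  d$length_c <- d$length_cm - mean(d$length_cm)
  d$sample <- factor(d$sample, levels = c("wild", "reared"))
  d
}

stage_fit <- function(cfg, out_dir, seed) {
  sc_path <- file.path(out_dir, "scores.csv")
  if (!file.exists(sc_path)) stop("missing input: ", sc_path)
  scores <- read.csv(sc_path)
  mc <- cfg$mcmc$univariate
  rows <- list(); txt <- character(0)
  for (ax in unique(scores$axis)) {
    d <- score_wide_for_axis(scores, ax)
    f <- reformulate(cfg$fixed_terms, response = "score")
    mcmc <- bt_mcmc(mc$n_iter, mc$burn_in, mc$thin,
                    seed = derive_seed(seed, match(ax, unique(scores$axis))))
    if (isTRUE(cfg$reduce)) {
      red <- backward_reduce(f, d, random = ~id, mcmc = mcmc)
      f <- red$formula
    }
    est <- repeatability_significance(f, d, random = ~id, mcmc = mcmc)
    s <- summary(est$fit)
    dg <- cfg$report$digits
    rows[[ax]] <- data.frame(
      axis = ax, term = c(rownames(s$fixed), "V_ind", "V_e", "adjusted_R"),
      post.mean = round(c(s$fixed$post.mean, s$vc$post.mean,
                          est$r_mean), dg),
      l.BCI = round(c(s$fixed$l.BCI, s$vc$l.BCI, est$bci[1]), dg),
      u.BCI = round(c(s$fixed$u.BCI, s$vc$u.BCI, est$bci[2]), dg),
      pMCMC = c(round(s$fixed$pMCMC, 3), NA, NA, NA),
      DIC = round(est$dic_full, 2), DIC_C = round(est$dic_constrained, 2),
      delta_DIC = round(est$delta_dic, 2), significant = est$significant)
    txt <- c(txt, sprintf(
      "%s: adjusted-R = %.2f [%.2f, %.2f]  DIC = %.2f (DIC_C = %.2f)%s",
      ax, est$r_mean, est$bci[1], est$bci[2], est$dic_full,
      est$dic_constrained, if (est$significant) " *" else ""))
  }
  t2 <- do.call(rbind, rows)
  t2_path <- file.path(out_dir, "table2_style.csv")
  write.csv(t2, t2_path, row.names = FALSE)
  txt_path <- file.path(out_dir, "table2_style.txt")
  writeLines(c("Variance decomposition per behavioral trait", txt), txt_path)
  manifest_add(out_dir, "fit", seed, sc_path, c(t2_path, txt_path))
}

stage_syndromes <- function(cfg, out_dir, seed) {
  sc_path <- file.path(out_dir, "scores.csv")
  if (!file.exists(sc_path)) stop("missing input: ", sc_path)
  scores <- read.csv(sc_path)
  mc <- cfg$mcmc$bivariate
  rows <- list(); txt <- character(0)
  for (k in seq_along(cfg$syndrome_pairs)) {
    pair <- unlist(cfg$syndrome_pairs[[k]])
    d1 <- score_wide_for_axis(scores, pair[1])
    d2 <- scores[scores$axis == pair[2], c("id", "trial", "score")]
    names(d2)[3] <- "score2"
    d <- merge(d1, d2, by = c("id", "trial"))
    names(d)[names(d) == "score"] <- "score1"
    f <- as.formula(paste("cbind(score1, score2) ~",
                          paste(cfg$fixed_terms, collapse = " + ")))
    syn <- bt_syndrome(f, d, random = ~id,
                       mcmc = bt_mcmc(mc$n_iter, mc$burn_in, mc$thin,
                                      seed = derive_seed(seed, k)))
    dg <- cfg$report$digits
    rows[[k]] <- data.frame(
      trait1 = pair[1], trait2 = pair[2],
      level = c("r_ind", "r_e", "r_p"),
      estimate = round(c(syn$r_ind[1], syn$r_e[1], syn$r_p[1]), dg),
      l.BCI = round(c(syn$r_ind[2], syn$r_e[2], syn$r_p[2]), dg),
      u.BCI = round(c(syn$r_ind[3], syn$r_e[3], syn$r_p[3]), dg),
      delta_DIC = round(syn$delta_dic, 2), significant = syn$significant)
    txt <- c(txt, sprintf(
      "%s--%s: r_ind = %.2f [%.2f, %.2f]  r_e = %.2f  r_p = %.2f  dDIC = %.2f%s",
      pair[1], pair[2], syn$r_ind[1], syn$r_ind[2], syn$r_ind[3],
      syn$r_e[1], syn$r_p[1], syn$delta_dic,
      if (syn$significant) " *" else ""))
  }
  t3 <- do.call(rbind, rows)
  t3_path <- file.path(out_dir, "table3_style.csv")
  write.csv(t3, t3_path, row.names = FALSE)
  txt_path <- file.path(out_dir, "table3_style.txt")
  writeLines(c("Between-/within-individual correlation decomposition",
               "(* = dDIC > 2 vs covariance-constrained model)", txt),
             txt_path)
  manifest_add(out_dir, "syndromes", seed, sc_path, c(t3_path, txt_path))
}

stage_report <- function(cfg, out_dir, seed) {
  parts <- c("table2_style.txt", "table3_style.txt")
  lines <- c("behavtype pipeline report", strrep("=", 40))
  for (p in parts) {
    fp <- file.path(out_dir, p)
    if (file.exists(fp)) lines <- c(lines, "", readLines(fp))
  }
  ld <- file.path(out_dir, "loadings.csv")
  if (file.exists(ld)) {
    lv <- read.csv(ld)
    vf <- unique(lv[c("axis", "variance_fraction")])
    lines <- c(lines, "", "PC1 variance fraction per axis:",
               sprintf("  %-12s %.3f", vf$axis, vf$variance_fraction))
  }
  rp <- file.path(out_dir, "report.txt")
  writeLines(lines, rp)
  manifest_add(out_dir, "report", seed,
               file.path(out_dir, parts), rp)
}
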