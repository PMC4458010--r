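# Dataset I/O, the Table-2-style analysis report, and the flat-file
# configuration runner.

#' Write a CRT dataset as delimited text
#'
#' One row per subject with header `cluster,arm,y` — the same schema
#' [read_trial_csv()] reads.
#'
#' @param data a [crt_data()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path) {
  stopifnot(inherits(data, "crt_data"))
  write.csv(as.data.frame(data), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a CRT dataset from delimited text
#'
#' Expects a header `cluster,arm,y`, with `arm` constant within each
#' cluster and `y` in {0, 1}.  Validation failures name the offending
#' clusters or rows.
#'
#' @param path input file path.
#' @return a validated [crt_data()] object.
#' @export
read_trial_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cluster", "arm", "y")
  if (!all(need %in% names(df)))
    stop("input must have columns `cluster`, `arm`, `y`; found: ",
         paste(names(df), collapse = ", "))
  crt_data(df$cluster, df$arm, df$y)
}

#' Analyse a CRT dataset with all five DDF approximations
#'
#' Fits the random-intercept logistic GLMM once and reports the
#' intervention-effect Wald F test under every DDF method, together with
#' a dataset summary and the ANOVA moment estimate of the ICC on the
#' binary scale.
#'
#' @param data a [crt_data()] object, a data frame with columns
#'   cluster/arm/y, or a path to a CSV file in that schema.
#' @param control fitting options ([glmm_control()]).
#' @param L contrast (default the arm effect).
#' @return an object of class `crt_analysis`: a list with `data_summary`,
#'   `icc`, `fit`, and `tests` (the [wald_tests()] table).
#' @export
analyze <- function(data, control = glmm_control(), L = c(0, 1)) {
  if (is.character(data)) data <- read_trial_csv(data)
  if (is.data.frame(data)) data <- crt_data(data$cluster, data$arm, data$y)
  stopifnot(inherits(data, "crt_data"))
  fit <- fit_glmm(data, control)
  tests <- wald_tests(fit, L = L)
  arm_of <- data$cluster_arm[data$cluster]
  summ <- list(
    K = data$K, N = data$N,
    clusters_control = sum(data$cluster_arm == 0L),
    clusters_intervention = sum(data$cluster_arm == 1L),
    n_control = sum(arm_of == 0L),
    n_intervention = sum(arm_of == 1L),
    rate_control = mean(data$y[arm_of == 0L]),
    rate_intervention = mean(data$y[arm_of == 1L]))
  structure(list(data_summary = summ,
                 icc = icc_anova(data$y, data$cluster),
                 fit = fit, tests = tests),
            class = "crt_analysis")
}

method_labels <- c(residual = "Residual", containment = "Containment",
                   between_within = "B-W", satterthwaite = "Satterthwaite",
                   kenward_roger = "K-R")

#' @export
print.crt_analysis <- function(x, digits = 4, ...) {
  s <- x$data_summary
  cat("GLMM small-sample inference of the intervention effect\n")
  cat(sprintf("  %d clusters (%d control / %d intervention), %d subjects (%d / %d)\n",
              s$K, s$clusters_control, s$clusters_intervention,
              s$N, s$n_control, s$n_intervention))
  cat(sprintf("  crude event rates: control %.4f, intervention %.4f\n",
              s$rate_control, s$rate_intervention))
  cat(sprintf("  estimated ICC (ANOVA moment): %.4f\n", x$icc))
  cat(sprintf("  tau2 = %.4f, phi = %.4f%s\n", x$fit$varcomp$tau2,
              x$fit$varcomp$phi,
              if (x$fit$converged) "" else "  [fit did not converge]"))
  tab <- x$tests
  out <- data.frame(Method = method_labels[tab$method],
                    Estimate = round(tab$estimate, digits),
                    SE = round(tab$se, digits),
                    F = round(tab$F, 3),
                    NumDF = tab$num_df,
                    DenDF = round(tab$ddf, 2),
                    p = round(tab$p_value, digits))
  print(out, row.names = FALSE)
  invisible(x)
}

config_keys <- list(
  common = c("mode", "seed", "out"),
  simulate = c("K", "nbar", "cv", "icc", "odds_ratio", "mu_control",
               "n_reps", "alpha", "methods"),
  analyze = c("data", "phi"))

#' Run a study or analysis declared in a flat configuration file
#'
#' The configuration is a flat key: value file (YAML scalar/sequence
#' syntax).  `mode: simulate` declares a scenario grid (each of `K`,
#' `nbar`, `cv`, `icc` may be a list of axis values, crossed into a
#' grid), a replication count and a master seed, and writes the long
#' results table to `out`.  `mode: analyze` reads the dataset at `data`,
#' runs [analyze()] and writes the report table to `out`.  Unknown keys
#' are an error; a missing seed is generated and reported.
#'
#' @param path path to the configuration file.
#' @param verbose print the execution plan and progress.
#' @return the results table (invisibly).
#' @export
run_config <- function(path, verbose = TRUE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$mode) || !cfg$mode %in% c("simulate", "analyze"))
    stop("config must declare `mode: simulate` or `mode: analyze`")
  allowed <- c(config_keys$common, config_keys[[cfg$mode]])
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$seed)) {
    cfg$seed <- sample.int(.Machine$integer.max - 1L, 1L)
    if (verbose) message("no seed in config; generated seed ", cfg$seed)
  }
  if (cfg$mode == "simulate") {
    grid <- scenario_grid(K = cfg$K %||% 10,
                          nbar = cfg$nbar %||% 50,
                          cv = cfg$cv %||% 0,
                          icc = cfg$icc %||% 0.01,
                          odds_ratio = cfg$odds_ratio %||% 1,
                          mu_control = cfg$mu_control %||% 0.25)
    # validate every scenario up front (errors before any simulation)
    for (i in seq_len(nrow(grid)))
      trial_scenario(grid$K[i], grid$nbar[i], grid$cv[i], grid$icc[i],
                     grid$mu_control[i], grid$odds_ratio[i])
    if (verbose)
      message(sprintf("plan: %d scenario(s) x %d replicate(s), master seed %d",
                      nrow(grid), cfg$n_reps %||% 1000, cfg$seed))
    res <- run_grid(grid, n_reps = cfg$n_reps %||% 1000,
                    methods = cfg$methods %||% all_ddf_methods(),
                    alpha = cfg$alpha %||% 0.05,
                    seed = cfg$seed, verbose = verbose)
  } else {
    if (is.null(cfg$data)) stop("`mode: analyze` requires a `data` path")
    ctrl <- if (!is.null(cfg$phi) && cfg$phi == "fixed")
      glmm_control(phi = "fixed") else glmm_control()
    rep <- analyze(cfg$data, control = ctrl)
    if (verbose) print(rep)
    res <- rep$tests
  }
  if (!is.null(cfg$out)) {
    write.csv(res, cfg$out, row.names = FALSE)
    if (verbose) message("results written to ", cfg$out)
  }
  invisible(res)
}
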