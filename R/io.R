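#' Read an unlabeled-fraction time-course CSV
#'
#' Expects columns `metabolite`, `time_s`, `value`, `variance`; duplicate
#' (metabolite, time) pairs, non-numeric values and nonpositive variances
#' are rejected with descriptive errors.
#'
#' @param path Path to the CSV file.
#' @return Tibble with the four validated columns.
#' @export
read_timecourse_csv <- function(path) {
  tc <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("metabolite", "time_s", "value", "variance")
  missing <- setdiff(need, names(tc))
  if (length(missing)) {
    stop("time-course file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  tc <- tc[need]
  for (col in c("time_s", "value", "variance")) {
    if (!is.numeric(tc[[col]])) {
      stop("column '", col, "' must be numeric")
    }
  }
  dup <- duplicated(tc[c("metabolite", "time_s")])
  if (any(dup)) {
    d <- tc[dup, ][1, ]
    stop(sprintf("duplicate (metabolite, time) pair: %s at %g s",
                 d$metabolite, d$time_s))
  }
  bad <- which(tc$variance <= 0)
  if (length(bad)) {
    stop(sprintf("nonpositive variance in row %d (%s at %g s)",
                 bad[1], tc$metabolite[bad[1]], tc$time_s[bad[1]]))
  }
  tc
}

#' Write a time-course tibble to CSV
#'
#' @param tc Tibble with columns `metabolite`, `time_s`, `value`,
#'   `variance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_timecourse_csv <- function(tc, path) {
  readr::write_csv(tc[c("metabolite", "time_s", "value", "variance")], path)
  invisible(path)
}

#' Read a compartmentalized-contents CSV
#'
#' @param path CSV with columns `pool`, `mean`, `std`.
#' @return Validated tibble.
#' @export
read_contents_csv <- function(path) {
  ct <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("pool", "mean", "std")
  missing <- setdiff(need, names(ct))
  if (length(missing)) {
    stop("contents file is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  ct <- ct[need]
  if (any(ct$mean <= 0)) stop("content means must be positive")
  if (any(ct$std <= 0)) stop("content standard deviations must be positive")
  ct
}

#' Read a RuBP mass-isotopomer CSV
#'
#' @param path CSV with columns `time_s`, `m0` .. `m5`.
#' @return Validated tibble (rows sum to 1).
#' @export
read_rubp_csv <- function(path) {
  rb <- readr::read_csv(path, show_col_types = FALSE)
  validate_mass_isotopomers(rb)
  rb
}

#' Assemble a dataset from its three component files
#'
#' @param timecourse_path,contents_path,rubp_path Paths to the time-course,
#'   contents and RuBP CSV files.
#' @return An `mfa_dataset`.
#' @export
read_dataset <- function(timecourse_path, contents_path, rubp_path = NULL) {
  tc <- read_timecourse_csv(timecourse_path)
  ct <- read_contents_csv(contents_path)
  rb <- if (!is.null(rubp_path)) read_rubp_csv(rubp_path) else NULL
  structure(
    list(timecourse = tc, contents = ct, rubp = rb,
         times = sort(unique(tc$time_s))),
    class = "mfa_dataset"
  )
}

#' Write a dataset to a directory of CSV files
#'
#' @param dataset An `mfa_dataset`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_timecourse_csv(dataset$timecourse, file.path(dir, "timecourse.csv"))
  readr::write_csv(dataset$contents, file.path(dir, "contents.csv"))
  if (!is.null(dataset$rubp)) {
    readr::write_csv(dataset$rubp, file.path(dir, "rubp.csv"))
  }
  invisible(dir)
}

#' Write a flux report CSV (flux-table layout)
#'
#' One row per reaction with net, forward and backward fluxes in C-atom
#' units; capped exchange fluxes are written as the string `"Inf."`.
#'
#' @param fd A `flux_distribution`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_flux_csv <- function(fd, path) {
  tb <- tidy(fd)
  fmt <- function(x, capped) ifelse(capped, "Inf.", format(x, digits = 6))
  out <- tibble::tibble(
    reaction = tb$reaction,
    net = format(tb$net, digits = 6),
    forward = fmt(tb$forward, tb$capped),
    backward = fmt(tb$backward, tb$capped),
    units = "nmol C gFW-1 s-1"
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write fit results as JSON
#'
#' @param fit An `mfa_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  payload <- list(
    scenario = fit$spec$scenario,
    vwss_t = fit$vwss_t, vwss_c = fit$vwss_c, vwss_all = fit$vwss_all,
    df = fit$df,
    chi2_interval = c(fit$chi2_lower, fit$chi2_upper),
    accepted = fit$vwss_all >= fit$chi2_lower &
      fit$vwss_all <= fit$chi2_upper,
    quantities = as.list(fit_quantities(fit)),
    seed = fit$seed, restarts = fit$restarts
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a run configuration file
#'
#' YAML configuration with paths, scenario, seeds, restart counts and
#' solver tolerances.
#'
#' @param path Path to a YAML file.
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- list(scenario = "A", restarts = 100, seed = 1,
                   replicates = 100, rtol = 1e-8, atol = 1e-10,
                   outdir = ".")
  modifyList(defaults, cfg)
}

#' Command-line style entry point
#'
#' Dispatches the pipeline stages from a character vector of arguments,
#' mirroring a shell interface: `synth` (generate a synthetic dataset),
#' `simulate` (noise-free forward simulation of a preset truth), `fit`
#' (fit a scenario), `mc-ci` (fit plus Monte-Carlo intervals),
#' `sensitivity` (fit plus one sensitivity record) and `report` (flux
#' table and goodness-of-fit verdict for a saved fit).  Intended for
#' scripted use via `Rscript -e`; the package functions remain the
#' primary interface.
#'
#' @param argv Character vector, e.g.
#'   `c("synth", "--preset", "table1_like", "--seed", "1", "--out", dir)`.
#' @return Integer exit status, invisibly: 0 on success, 1 on a data or
#'   usage error, 2 on a convergence error.
#' @export
run_command <- function(argv) {
  usage <- paste(
    "usage: synth --preset <table1_like|random> --seed <int> --out <dir>",
    "       simulate --preset <table1_like|random> --seed <int> --out <csv>",
    "       fit --data <dir> --scenario <A|B|C> --restarts <int> --seed <int> --out <dir>",
    "       mc-ci --data <dir> --scenario <A|B|C> --replicates <int> --seed <int> --out <dir>",
    "       sensitivity --data <dir> --scenario <B> --pool <id> --quantity <name> --out <dir>",
    "       report --fit <fit.json>",
    sep = "\n")
  if (length(argv) < 1) {
    message(usage)
    return(invisible(1L))
  }
  opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) == 1 && i < length(argv)) argv[i + 1] else default
  }
  cmd <- argv[1]
  status <- tryCatch({
    switch(cmd,
      synth = {
        truth <- make_truth(seed = as.integer(opt("--seed", "1")),
                            preset = opt("--preset", "table1_like"),
                            noise_cv = as.numeric(opt("--noise-cv", "0.05")))
        gen <- make_dataset(truth, seed = as.integer(opt("--seed", "1")))
        out <- opt("--out", "dataset")
        write_dataset(gen$dataset, out)
        jsonlite::write_json(
          list(weights = as.list(truth$weights), phi = as.list(truth$phi),
               contents = as.list(truth$contents), seed = truth$seed),
          file.path(out, "truth.json"), auto_unbox = TRUE, digits = NA)
        message("wrote dataset to ", out)
        0L
      },
      simulate = {
        truth <- make_truth(seed = as.integer(opt("--seed", "1")),
                            preset = opt("--preset", "table1_like"))
        gen <- make_dataset(truth, noise_cv = 0)
        out <- opt("--out", "predicted.csv")
        write_timecourse_csv(gen$dataset$timecourse, out)
        message("wrote noise-free predictions to ", out)
        0L
      },
      `mc-ci` = {
        dir <- opt("--data")
        if (is.null(dir)) stop("mc-ci: --data is required")
        ds <- read_dataset(file.path(dir, "timecourse.csv"),
                           file.path(dir, "contents.csv"),
                           file.path(dir, "rubp.csv"))
        fit <- fit_scenario(ds, opt("--scenario", "A"),
                            restarts = as.integer(opt("--restarts", "12")),
                            seed = as.integer(opt("--seed", "1")))
        ci <- monte_carlo_ci(fit,
                             replicates =
                               as.integer(opt("--replicates", "100")),
                             seed = as.integer(opt("--seed", "1")) + 1)
        out <- opt("--out", "mc")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        readr::write_csv(tibble::as_tibble(ci), file.path(out, "ci.csv"))
        write_fit_json(fit, file.path(out, "fit.json"))
        message("wrote confidence report to ", out)
        0L
      },
      sensitivity = {
        dir <- opt("--data")
        if (is.null(dir)) stop("sensitivity: --data is required")
        ds <- read_dataset(file.path(dir, "timecourse.csv"),
                           file.path(dir, "contents.csv"),
                           file.path(dir, "rubp.csv"))
        fits <- fit_pipeline(ds, c("A", opt("--scenario", "B")),
                             restarts = as.integer(opt("--restarts", "12")),
                             seed = as.integer(opt("--seed", "1")))
        fit <- fits[[length(fits)]]
        rec <- local_sensitivity(fit, opt("--pool", "Tre6P"),
                                 opt("--quantity", "weight_trehalose"),
                                 seed = as.integer(opt("--seed", "1")))
        out <- opt("--out", "sensitivity")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        readr::write_csv(tibble::as_tibble(rec),
                         file.path(out, "sensitivity.csv"))
        message("wrote sensitivity record to ", out)
        0L
      },
      fit = {
        dir <- opt("--data")
        if (is.null(dir)) stop("fit: --data is required")
        ds <- read_dataset(file.path(dir, "timecourse.csv"),
                           file.path(dir, "contents.csv"),
                           file.path(dir, "rubp.csv"))
        fit <- fit_scenario(ds, opt("--scenario", "A"),
                            restarts = as.integer(opt("--restarts", "100")),
                            seed = as.integer(opt("--seed", "1")))
        out <- opt("--out", "fit")
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_fit_json(fit, file.path(out, "fit.json"))
        write_flux_csv(fit$flux, file.path(out, "fluxes.csv"))
        message("wrote fit to ", out)
        0L
      },
      report = {
        f <- opt("--fit")
        if (is.null(f)) stop("report: --fit is required")
        fit <- jsonlite::read_json(f, simplifyVector = TRUE)
        verdict <- if (isTRUE(fit$accepted)) "ACCEPTED" else "REJECTED"
        message(sprintf(
          "scenario %s: VWSS_all = %.4g, interval [%.0f, %.0f] -> %s",
          fit$scenario, fit$vwss_all, fit$chi2_interval[1],
          fit$chi2_interval[2], verdict))
        0L
      },
      {
        message("unknown subcommand: ", cmd, "\n", usage)
        1L
      }
    )
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("converge|restart", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}

#' Serialize a network to a structured text model file
#'
#' Writes pools (id, metabolite, compartment, carbons, role) and reactions
#' (stoichiometry in C atoms, reversibility, CO2 release and the
#' unlabeled-production rules) as YAML.
#'
#' @param network An `mfa_network`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network_model <- function(network, path) {
  pools <- lapply(seq_len(nrow(network$pools)), function(i) {
    as.list(network$pools[i, ])
  })
  rxns <- lapply(seq_len(nrow(network$reactions)), function(i) {
    r <- network$reactions[i, ]
    list(
      id = r$id, reversible = r$reversible, release_c = r$release,
      substrates = as.list(r$sub[[1]]), products = as.list(r$prod[[1]]),
      unlabeled_production = lapply(r$hrules[[1]], function(terms) {
        lapply(terms, function(tm) {
          list(weight = tm$w, factors = as.list(tm$f))
        })
      })
    )
  })
  yaml::write_yaml(list(pools = pools, reactions = rxns), path)
  invisible(path)
}
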