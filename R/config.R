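# YAML run configurations: a declarative surface over the optimizers,
# producing designs, certificates and sensitivity grids on disk.

config_allowed <- list(
  top = c("model", "search", "output"),
  # "n_individuals"/"m_observations" rather than bare n/m: YAML 1.1
  # resolves the keys "n" and "y" as booleans
  model = c("family", "basis", "D", "n_individuals", "m_observations",
            "sigma2", "beta", "lower", "upper"),
  basis = c("type", "degree", "powers", "dim", "intercept", "interactions",
            "strict"),
  search = c("criterion", "k", "swarm", "max_iter", "gamma", "tol",
             "restarts", "seed", "fixed_support"),
  output = c("dir", "grid_n")
)

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra)) {
    stop("Unknown key(s) in ", where, ": ", paste(extra, collapse = ", "),
         ". Allowed: ", paste(allowed, collapse = ", "), ".")
  }
}

config_basis <- function(spec) {
  check_keys(spec, config_allowed$basis, "model$basis")
  type <- spec$type %||% stop("`model$basis$type` is required.")
  switch(type,
    poly = poly_basis(spec$degree %||% stop("poly basis needs `degree`.")),
    fp = fp_basis(unlist(spec$powers %||% stop("fp basis needs `powers`.")),
                  intercept = spec$intercept %||% TRUE,
                  strict = spec$strict %||% TRUE),
    factor = factor_basis(spec$dim %||% stop("factor basis needs `dim`."),
                          intercept = spec$intercept %||% TRUE,
                          interactions = lapply(spec$interactions %||% list(),
                                                unlist)),
    stop("Unknown basis type `", type, "` (poly, fp or factor).")
  )
}

config_matrix <- function(x, p, name) {
  if (is.null(x)) stop("`", name, "` is required.")
  M <- do.call(rbind, lapply(x, unlist))
  if (nrow(M) != p || ncol(M) != p) {
    stop("`", name, "` must be ", p, " x ", p, " (nested numeric lists).")
  }
  # symmetry completion from the upper triangle
  M[lower.tri(M)] <- t(M)[lower.tri(M)]
  M
}

#' Load and validate a run configuration
#'
#' A YAML document with `model`, `search` and `output` sections defines
#' a complete design problem: the model family (`hierarchical-linear` or
#' `poisson-mixed`), its basis, dispersion matrix `D` (nested lists;
#' upper triangle suffices), the counts `n_individuals` and
#' `m_observations`, design-space bounds and -- for
#' Poisson models -- the nominal `beta`; the search criterion (`G` or
#' `D`), swarm tuning and seed; and the output directory.  Unknown keys
#' are rejected.  Defaults mirror the package's search defaults (128
#' particles, 350 iterations, \eqn{\gamma = 0}, tolerance `1e-6`).
#'
#' @param path Path to a YAML file.
#' @return A validated `run_config` list with a constructed `model`
#'   object.
#' @export
read_design_config <- function(path) {
  raw <- yaml::read_yaml(path)
  check_keys(raw, config_allowed$top, "config")
  ms <- raw$model %||% stop("Config needs a `model` section.")
  check_keys(ms, config_allowed$model, "model")
  ss <- raw$search %||% list()
  check_keys(ss, config_allowed$search, "search")
  os <- raw$output %||% list()
  check_keys(os, config_allowed$output, "output")

  basis <- config_basis(ms$basis %||% stop("`model$basis` is required."))
  space <- design_space(unlist(ms$lower %||% stop("`model$lower` required.")),
                        unlist(ms$upper %||% stop("`model$upper` required.")))
  family <- ms$family %||% "hierarchical-linear"
  D <- config_matrix(ms$D, basis$p, "model$D")
  model <- switch(family,
    "hierarchical-linear" = hlm_model(
      basis, D,
      n = ms$n_individuals %||% stop("`model$n_individuals` is required."),
      m = ms$m_observations %||% stop("`model$m_observations` is required."),
      space = space, sigma2 = ms$sigma2 %||% 1),
    "poisson-mixed" = poisson_model(
      basis, beta = unlist(ms$beta %||% stop("`model$beta` is required.")),
      D = D, space = space),
    stop("Unknown model family `", family, "`."))

  structure(list(
    model = model,
    criterion = toupper(ss$criterion %||% "G"),
    k = ss$k,
    cso = cso_config(swarm = ss$swarm %||% 128L,
                     max_iter = ss$max_iter %||% 350L,
                     gamma = ss$gamma %||% 0,
                     tol = ss$tol %||% 1e-6),
    restarts = ss$restarts %||% 5L,
    seed = ss$seed %||% 1L,
    fixed_support = if (!is.null(ss$fixed_support)) {
      do.call(rbind, lapply(ss$fixed_support, unlist))
    },
    out_dir = os$dir %||% ".",
    grid_n = os$grid_n %||% 501L
  ), class = "run_config")
}

#' Run a design search from a configuration
#'
#' Executes the configured search and writes its artifacts: the design
#' (`design.tsv`), a plain-text report (`report.txt`), the sensitivity
#' grid (`sensitivity.csv`, hierarchical G searches only) and the
#' per-iteration best-value log (`history.log`).
#'
#' @param config A `run_config` from [read_design_config()], or a path
#'   to a YAML file.
#' @param out_dir Output directory (overrides the config).
#' @param seed Seed (overrides the config).
#' @return The fitted `design_fit`, invisibly.
#' @export
run_design_config <- function(config, out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- read_design_config(config)
  stopifnot(inherits(config, "run_config"))
  out_dir <- out_dir %||% config$out_dir
  seed <- seed %||% config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- config$model

  fit <- if (inherits(model, "poisson_model")) {
    find_locally_d_optimal_poisson(model, k = config$k, config = config$cso,
                                   restarts = config$restarts, seed = seed)
  } else if (config$criterion == "D") {
    find_d_optimal_pred(model, k = config$k, config = config$cso,
                        restarts = config$restarts, seed = seed)
  } else {
    find_g_optimal(model, k = config$k,
                   fixed_support = config$fixed_support,
                   outer = config$cso, restarts = config$restarts,
                   seed = seed)
  }

  write_design(fit$design, file.path(out_dir, "design.tsv"))
  writeLines(format(fit$history, digits = 10),
             file.path(out_dir, "history.log"))
  rpt <- utils::capture.output({
    print(fit)
    if (!is.null(fit$report)) print(fit$report)
  })
  writeLines(rpt, file.path(out_dir, "report.txt"))
  if (!is.null(fit$report)) {
    grid <- sensitivity_grid(fit$report, model, n = config$grid_n)
    utils::write.csv(grid, file.path(out_dir, "sensitivity.csv"),
                     row.names = FALSE)
  }
  invisible(fit)
}
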