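# Minimal TOML subset reader: [section] headers and key = value lines
# with strings, numbers, booleans and flat arrays. Enough for run
# configs; not a general TOML implementation.
parse_toml_value <- function(txt, key) {
  txt <- trimws(txt)
  if (txt == "") stop("empty value for key `", key, "`")
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(substr(txt, 2, nchar(txt) - 1))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, parse_toml_value, key = key)))
  }
  if (grepl('^".*"$', txt)) return(substr(txt, 2, nchar(txt) - 1))
  if (grepl("^'.*'$", txt)) return(substr(txt, 2, nchar(txt) - 1))
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  stop("cannot parse value `", txt, "` for key `", key, "`")
}

read_toml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  for (raw in lines) {
    line <- sub("#.*$", "", raw)
    line <- trimws(line)
    if (line == "") next
    if (grepl("^\\[[A-Za-z0-9_.-]+\\]$", line)) {
      section <- substr(line, 2, nchar(line) - 1)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(m) != 3L)
      stop("cannot parse config line: ", raw)
    key <- m[2]; val <- parse_toml_value(m[3], m[2])
    if (is.null(section)) out[[key]] <- val
    else out[[section]][[key]] <- val
  }
  out
}

default_field <- function(block, key, default, log_fun) {
  if (is.null(block[[key]])) {
    log_fun(sprintf("config: `%s` not given, default %s applied", key,
                    paste(format(default), collapse = ", ")))
    default
  } else block[[key]]
}

check_domain <- function(value, key, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(value) && length(value) == 1L && is.finite(value) &&
    (if (open_lower) value > lower else value >= lower) &&
    (if (open_upper) value < upper else value <= upper)
  if (!ok)
    stop("config key `", key, "` out of domain ",
         if (open_lower) "(" else "[", lower, ", ", upper,
         if (open_upper) ")" else "]", ": got ", format(value))
  value
}

#' Load and validate a run configuration
#'
#' Reads a TOML config with blocks `[model]` (mu, sigma2, p_tilde, K),
#' `[rates]` (inflow, learning, outflow, phi) and `[command]` (name plus
#' command-specific options). Missing keys get documented defaults
#' (logged via `message`): the coordination-dilemma threshold
#' distribution mu = 0.5, sigma2 = 0.04, K = 1, p_tilde = "auto" (the
#' high-cooperation root of the Normal(0.5, 0.04) reference), unit
#' rates. Unknown keys and out-of-domain values raise errors naming the
#' offending key.
#'
#' @param path path to the TOML config file.
#' @param quiet suppress default-application messages.
#' @return a list of class `run_config` with elements `params`
#'   ([community_params()]), `command` (name) and `options`
#'   (command-specific options).
#' @export
load_config <- function(path, quiet = FALSE) {
  raw <- read_toml(path)
  log_fun <- if (quiet) function(...) invisible() else message
  known_blocks <- c("model", "rates", "command")
  extra <- setdiff(names(raw), known_blocks)
  if (length(extra))
    stop("unknown config block(s): ", paste(extra, collapse = ", "))

  model <- raw$model %||0% list()
  rates <- raw$rates %||0% list()
  command <- raw$command %||0% list()

  chk_keys <- function(block, name, allowed) {
    bad <- setdiff(names(block), allowed)
    if (length(bad))
      stop("unknown key(s) in [", name, "]: ", paste(bad, collapse = ", "))
  }
  chk_keys(model, "model", c("mu", "sigma2", "p_tilde", "K",
                             "reference_mu", "reference_sigma2"))
  chk_keys(rates, "rates", c("inflow", "learning", "outflow", "phi"))
  chk_keys(command, "command",
           c("name", "initial", "t_end", "n_samples", "parameter",
             "values", "grid_from", "grid_to", "grid_n",
             "sigma2_values", "transient_fraction"))

  mu <- check_domain(default_field(model, "mu", 0.5, log_fun), "mu",
                     0, 1, TRUE, TRUE)
  sigma2 <- check_domain(default_field(model, "sigma2", 0.04, log_fun),
                         "variance (sigma2)", 0, Inf, TRUE)
  K <- check_domain(default_field(model, "K", 1, log_fun), "K", 0, Inf, TRUE)
  ref_mu <- check_domain(default_field(model, "reference_mu", 0.5, log_fun),
                         "reference_mu", 0, 1, TRUE, TRUE)
  ref_s2 <- check_domain(default_field(model, "reference_sigma2", 0.04,
                                       log_fun),
                         "reference_sigma2", 0, Inf, TRUE)
  p_tilde <- default_field(model, "p_tilde", "auto", log_fun)
  if (!identical(p_tilde, "auto"))
    check_domain(p_tilde, "p_tilde", 0, 1, TRUE, FALSE)

  inflow <- check_domain(default_field(rates, "inflow", 1, log_fun),
                         "inflow", 0)
  learning <- check_domain(default_field(rates, "learning", 1, log_fun),
                           "learning", 0)
  outflow <- check_domain(default_field(rates, "outflow", 1, log_fun),
                          "outflow", 0)
  phi <- check_domain(default_field(rates, "phi", 1, log_fun), "phi", 0)

  cmd <- default_field(command, "name", "simulate", log_fun)
  cmds <- c("simulate", "equilibria", "scan", "regime", "cycles")
  if (!cmd %in% cmds)
    stop("config key `name` must be one of ",
         paste(cmds, collapse = ", "), "; got `", cmd, "`")

  params <- community_params(inflow, learning, outflow, phi, K = K,
                             p_tilde = p_tilde,
                             norms = norm_sensitivity(mu, sigma2),
                             reference = norm_sensitivity(ref_mu, ref_s2))

  opts <- command[setdiff(names(command), "name")]
  structure(list(params = params, command = cmd, options = opts),
            class = "run_config")
}

`%||0%` <- function(a, b) if (is.null(a)) b else a

#' Run a validated configuration
#'
#' Dispatches to the named command and writes its artifacts under
#' `out_dir`: `trajectory.csv` (simulate, cycles),
#' `equilibria.json` (equilibria), `scan.csv` + `folds.json` (scan),
#' `regime.json` (regime), `cycles.json` (cycles). Floating-point
#' output uses 17 significant digits so repeated runs of the same
#' config are byte-identical.
#'
#' @param config a `run_config` from [load_config()].
#' @param out_dir output directory (created if absent).
#' @param seed RNG seed used only when the config requests random
#'   initial conditions (`initial = "random"`).
#' @param quiet suppress progress messages.
#' @return invisibly, a character vector of the files written.
#' @export
run_config <- function(config, out_dir = ".", seed = 1L, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  log_fun <- if (quiet) function(...) invisible() else message
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- config$params
  opts <- config$options
  written <- character(0)
  t0 <- proc.time()[["elapsed"]]

  get_initial <- function() {
    init <- opts$initial %||0% c(0.99 * params$K, 0.01 * params$K, 0, 0)
    if (identical(init, "random")) {
      set.seed(as.integer(seed))
      sfrac <- stats::runif(1, 0.2, 0.95)
      ifrac <- stats::runif(1, 0.01, 1 - sfrac)
      init <- c(sfrac * params$K, ifrac * params$K, stats::runif(1),
                stats::runif(1, 0, params$p_tilde))
    }
    if (length(init) != 4L)
      stop("config key `initial` must be (S, I, y, p) or \"random\"")
    community_state(init[1], init[2], init[3], init[4], K = params$K)
  }

  if (config$command == "simulate" || config$command == "cycles") {
    t_end <- check_domain(opts$t_end %||0% 100, "t_end", 0, Inf, TRUE)
    n_samples <- as.integer(opts$n_samples %||0%
                              max(501, min(20000, 10 * t_end)))
    traj <- integrate_community(params, get_initial(), t_end,
                                n_samples = n_samples)
    f <- file.path(out_dir, "trajectory.csv")
    write_trajectory_csv(traj, f)
    written <- c(written, f)
    if (config$command == "cycles") {
      tf <- opts$transient_fraction %||0% 0.5
      cyc <- classify_attractor(traj, transient_fraction = tf)
      f <- file.path(out_dir, "cycles.json")
      writeLines(jsonlite::toJSON(
        list(classification = cyc$classification, period = cyc$period,
             n_peaks = cyc$n_peaks, amplitude_drift = cyc$amplitude_drift,
             ranges = as.data.frame(cyc$ranges)),
        auto_unbox = TRUE, digits = NA, na = "null"), f)
      written <- c(written, f)
    }
  } else if (config$command == "equilibria") {
    eqs <- enumerate_equilibria(params)
    f <- file.path(out_dir, "equilibria.json")
    equilibria_json(eqs, f)
    written <- c(written, f)
  } else if (config$command == "scan") {
    parameter <- opts$parameter %||0%
      stop("scan command requires config key `parameter`")
    values <- opts$values
    if (is.null(values)) {
      if (is.null(opts$grid_from) || is.null(opts$grid_to))
        stop("scan command requires `values` or `grid_from`/`grid_to`")
      values <- seq(opts$grid_from, opts$grid_to,
                    length.out = as.integer(opts$grid_n %||0% 51))
    }
    sc <- scan_equilibria(params, parameter, values)
    f1 <- file.path(out_dir, "scan.csv")
    write_scan_csv(sc, f1)
    f2 <- file.path(out_dir, "folds.json")
    writeLines(jsonlite::toJSON(sc$folds, digits = NA, dataframe = "rows"),
               f2)
    written <- c(written, f1, f2)
  } else if (config$command == "regime") {
    s2v <- opts$sigma2_values
    if (is.null(s2v)) stop("regime command requires `sigma2_values`")
    rd <- regime_diagram(params$norms$mean, s2v, params$p_tilde)
    f <- file.path(out_dir, "regime.json")
    writeLines(jsonlite::toJSON(rd, digits = NA, dataframe = "rows",
                                na = "null"), f)
    written <- c(written, f)
  }
  log_fun(sprintf("command `%s` finished in %.2f s; wrote: %s",
                  config$command, proc.time()[["elapsed"]] - t0,
                  paste(basename(written), collapse = ", ")))
  invisible(written)
}
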