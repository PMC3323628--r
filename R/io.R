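# Configuration parsing, deterministic table output, and the synthetic
# fixture generator.

.config_keys <- list(
  top = c("polymerase", "tfs", "factors", "energies", "task", "output",
          "seed", "log_level"),
  polymerase = c("relative_concentration", "concentration", "kd"),
  tf = c("name", "relative_concentration", "concentration", "kd"),
  factors = c("w", "omega_tf", "omega_3"),
  energies = c("delta_e", "delta_e_pair", "delta_e3", "temperature", "units")
)

.reject_unknown <- function(block, allowed, where) {
  extra <- setdiff(names(block), allowed)
  if (length(extra))
    stop("unknown key '", extra[1], "' in ", where, " configuration",
         call. = FALSE)
}

#' Load and validate a model configuration
#'
#' Reads a YAML or JSON configuration describing a promoter model: a
#' `polymerase` block (relative concentration, or concentration + kd), an
#' optional list of `tfs` (same dose fields plus `name`), and either a
#' `factors` block (`w`, `omega_tf`, `omega_3`, each a mapping) or an
#' `energies` block (`delta_e`, `delta_e_pair`, `delta_e3`, `temperature`,
#' `units`) — never both. Task/output/seed/log_level blocks are validated for
#' key names and passed through. Unknown keys are rejected with a message
#' naming the key. A minimal configuration needs only the polymerase dose;
#' factors then default to 1 (temperature 298.15 K).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An object of class `run_config`: list with `polymerase`
#'   ([polymerase_dose()]), `tfs` (list of [activator_dose()]), `factors`
#'   ([cooperativity_parameters()]), and the raw `task`, `output`, `seed`,
#'   `log_level` entries.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
                yaml = , yml = yaml::read_yaml(path),
                json = jsonlite::fromJSON(path, simplifyVector = TRUE,
                                          simplifyDataFrame = FALSE,
                                          simplifyMatrix = FALSE),
                stop("unsupported configuration format: .", ext))
  if (!is.list(raw)) stop("configuration must be a mapping")
  .reject_unknown(raw, .config_keys$top, "top-level")
  if (!is.null(raw$factors) && !is.null(raw$energies))
    stop("'factors' and 'energies' are mutually exclusive")
  if (is.null(raw$polymerase))
    stop("configuration requires a 'polymerase' block")
  .reject_unknown(raw$polymerase, .config_keys$polymerase, "'polymerase'")
  pol <- do.call(polymerase_dose, raw$polymerase)
  tfs <- lapply(raw$tfs, function(tf) {
    .reject_unknown(tf, .config_keys$tf, "'tfs'")
    do.call(activator_dose, tf)
  })
  tf_names <- vapply(tfs, `[[`, character(1), "name")
  if (anyDuplicated(tf_names)) stop("duplicate TF name in 'tfs'")
  factors <- if (!is.null(raw$energies)) {
    .reject_unknown(raw$energies, .config_keys$energies, "'energies'")
    en <- raw$energies
    factors_from_energies(energy_parameters(
      delta_e = unlist(en$delta_e),
      delta_e_pair = if (length(en$delta_e_pair)) unlist(en$delta_e_pair),
      delta_e3 = if (length(en$delta_e3)) unlist(en$delta_e3),
      temperature = if (is.null(en$temperature)) 298.15 else en$temperature,
      units = if (is.null(en$units)) "kcal/mol" else en$units))
  } else if (!is.null(raw$factors)) {
    .reject_unknown(raw$factors, .config_keys$factors, "'factors'")
    fb <- raw$factors
    cooperativity_parameters(
      w = unlist(fb$w),
      omega_tf = if (length(fb$omega_tf)) unlist(fb$omega_tf),
      omega3 = if (length(fb$omega_3)) unlist(fb$omega_3))
  } else {
    cooperativity_parameters(
      stats::setNames(rep(1, length(tf_names)), tf_names))
  }
  missing_w <- setdiff(tf_names, names(factors$w))
  if (length(missing_w)) {
    w <- factors$w
    w[missing_w] <- 1
    factors <- cooperativity_parameters(w[tf_names],
                                        .subset_pairs(factors$omega_tf, tf_names),
                                        .subset_pairs(factors$omega3, tf_names))
  }
  structure(
    list(polymerase = pol, tfs = tfs, factors = factors,
         task = raw$task, output = raw$output, seed = raw$seed,
         log_level = if (is.null(raw$log_level)) "info" else raw$log_level),
    class = "run_config"
  )
}

.subset_pairs <- function(x, tf_names) {
  if (is.null(x) || !length(x)) return(NULL)
  keep <- vapply(strsplit(names(x), ":", fixed = TRUE),
                 function(p) all(p %in% tf_names), logical(1))
  if (!any(keep)) NULL else x[keep]
}

#' Write a deterministic TSV table
#'
#' Writes a data frame as tab-separated text with one header line, doubles
#' formatted as `%.12g`, `.` as the decimal separator, `\n` line endings and
#' UTF-8 encoding. Identical inputs produce byte-identical files.
#'
#' @param rows Data frame.
#' @param path Output path (or `""`/`"-"` for standard output).
#' @return Invisibly, the path.
#' @export
write_table <- function(rows, path) {
  if (!is.data.frame(rows)) stop("'rows' must be a data frame")
  fmt_col <- function(v) {
    if (is.double(v)) sprintf("%.12g", v)
    else if (is.logical(v)) ifelse(v, "TRUE", "FALSE")
    else as.character(v)
  }
  header <- paste(names(rows), collapse = "\t")
  body <- if (nrow(rows))
    do.call(paste, c(lapply(rows, fmt_col), sep = "\t"))
  else character(0)
  lines <- c(header, body)
  if (identical(path, "") || identical(path, "-")) {
    writeLines(lines)
  } else {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
  }
  invisible(path)
}

#' Generate synthetic fold-change fixtures
#'
#' Emulates saturation reporter-assay readouts for a panel of two-activator
#' promoters: truth parameters are drawn log-uniformly, noiseless fold
#' changes are computed from the forward model at low polymerase dose and
#' saturating stimulation ([fold_change()]), and multiplicative lognormal
#' measurement noise is applied. Truth columns are retained so estimates can
#' be checked for recovery. This generator is the only source of randomness
#' in the package; regenerating with the same seed reproduces identical
#' tables.
#'
#' @param seed Integer RNG seed (required).
#' @param n Number of promoters in the panel.
#' @param w_range Range for the log-uniform draw of `w_A` and `w_B`.
#' @param omega3_range Range for the log-uniform draw of `omega3`.
#' @param noise_sd Standard deviation (log scale) of the multiplicative
#'   lognormal noise; 0 gives exact forward-model fold changes.
#' @param x_P Relative polymerase dose of the emulated assay (default 1e-6,
#'   the low-polymerase regime the estimator assumes).
#' @return An object of class `fixture_set`: list with `parameters` (truth
#'   table), `fold_changes` (long table with `promoter_id`, `condition`,
#'   `fold_change`, `true_fold_change`) and `manifest` (seed, sizes, ranges,
#'   generator version).
#' @examples
#' fx <- generate_fixtures(seed = 1, n = 5, noise_sd = 0)
#' fx$fold_changes[fx$fold_changes$promoter_id == 1, ]
#' @export
generate_fixtures <- function(seed, n = 100, w_range = c(1, 50),
                              omega3_range = c(0.5, 20), noise_sd = 0.1,
                              x_P = 1e-6) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("an integer 'seed' is required")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("'noise_sd' must be >= 0")
  for (r in list(w_range, omega3_range))
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2])
      stop("invalid fixture parameter range")
  set.seed(as.integer(seed))
  runif_log <- function(k, r) exp(stats::runif(k, log(r[1]), log(r[2])))
  truth <- data.frame(
    promoter_id = seq_len(n),
    w_A = runif_log(n, w_range),
    w_B = runif_log(n, w_range),
    omega3 = runif_log(n, omega3_range)
  )
  fc <- do.call(rbind, lapply(seq_len(n), function(i) {
    sys <- two_activator_system(x_P, 0, 0, truth$w_A[i], truth$w_B[i],
                                omega3 = truth$omega3[i])
    f <- fold_change(sys)
    data.frame(promoter_id = i,
               condition = c("A_only", "B_only", "dual"),
               true_fold_change = as.numeric(f),
               stringsAsFactors = FALSE)
  }))
  noise <- if (noise_sd > 0)
    stats::rlnorm(nrow(fc), meanlog = 0, sdlog = noise_sd)
  else rep(1, nrow(fc))
  fc$fold_change <- fc$true_fold_change * noise
  fc <- fc[, c("promoter_id", "condition", "fold_change", "true_fold_change")]
  structure(
    list(parameters = truth, fold_changes = fc,
         manifest = list(seed = as.integer(seed), n = n,
                         w_range = w_range, omega3_range = omega3_range,
                         noise_sd = noise_sd, x_P = x_P,
                         generator_version = "1")),
    class = "fixture_set"
  )
}

#' @export
print.fixture_set <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "Fixture set: %d promoters (seed %d, noise sd %g, x_P %g, generator v%s)\n",
    m$n, m$seed, m$noise_sd, m$x_P, m$generator_version))
  invisible(x)
}
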