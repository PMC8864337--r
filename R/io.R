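#' Read a direction sample from CSV
#'
#' Accepts the three column dialects: `angle` (circle), `theta1,theta2`
#' (sphere, spherical coordinates) or `x,y,z` (sphere, Cartesian unit
#' vectors). Lines starting with `#` (provenance headers) are skipped.
#'
#' @param path CSV file with a header row.
#' @param unit `"rad"` (default) or `"deg"`; ignored for Cartesian input.
#' @return a [direction_sample()].
#' @export
read_directions <- function(path, unit = c("rad", "deg")) {
  unit <- match.arg(unit)
  df <- utils::read.csv(path, comment.char = "#")
  conv <- if (unit == "deg") pi / 180 else 1
  if (all(c("x", "y", "z") %in% names(df))) {
    X <- as.matrix(df[, c("x", "y", "z")])
    nrm <- sqrt(rowSums(X^2))
    if (any(abs(nrm - 1) > 1e-6)) stop("x,y,z rows must be unit vectors")
    direction_sample(to_angles(X / nrm), p = 3L)
  } else if (all(c("theta1", "theta2") %in% names(df))) {
    direction_sample(cbind(df$theta1, df$theta2) * conv, p = 3L)
  } else if ("angle" %in% names(df)) {
    direction_sample(df$angle * conv)
  } else {
    stop("missing columns: need `angle`, `theta1,theta2` or `x,y,z`")
  }
}

# cheap deterministic content hash for provenance headers
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  sprintf("%08x", as.integer(h))
}

provenance_header <- function(seed = NULL, config = NULL) {
  c(sprintf("# skewsphere %s",
            as.character(utils::packageVersion("skewsphere"))),
    if (!is.null(seed)) sprintf("# seed: %s", format(seed)),
    if (!is.null(config)) sprintf("# config: %s", config_hash(config)))
}

#' Write a direction sample to CSV
#'
#' Writes the angular dialect read by [read_directions()], preceded by a
#' provenance comment header (package version, seed, configuration hash).
#'
#' @param x a [direction_sample()].
#' @param path output path.
#' @param unit `"rad"` or `"deg"`.
#' @param seed,config optional provenance fields.
#' @return `path`, invisibly.
#' @export
write_directions <- function(x, path, unit = c("rad", "deg"), seed = NULL,
                             config = NULL) {
  unit <- match.arg(unit)
  stopifnot(inherits(x, "direction_sample"))
  ang <- unclass_angles(x)
  if (unit == "deg") ang <- ang * 180 / pi
  df <- as.data.frame(ang)
  names(df) <- if (unit_p(x) == 2L) "angle" else c("theta1", "theta2")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a scenario configuration file
#'
#' Flat YAML key-value file, e.g. `scenario: 3`, `mu0: [1.0]`, `tau0: 9`,
#' `alpha: 0.5`, `beta: 5`, `xi: [-4]`, `sigma: [1]`, optional
#' `lambda: [...]`, plus chain settings `k`, `burnin`, `N`, `seed`.
#'
#' @param path YAML file.
#' @return list with `spec` (a [scenario_spec()]) and `chain`
#'   (list `B`, `N`, `k`, `seed`).
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$scenario)) stop("config is missing `scenario`")
  p <- cfg$p %||% 2L
  spec <- scenario_spec(scenario = cfg$scenario, p = p,
                        mu0 = unlist(cfg$mu0), zeta = cfg$zeta,
                        eta = cfg$eta, tau0 = unlist(cfg$tau0),
                        alpha = cfg$alpha, beta = cfg$beta,
                        xi = unlist(cfg$xi) %||% 0,
                        sigma = unlist(cfg$sigma) %||% 1,
                        lambda = unlist(cfg$lambda),
                        tau_max = cfg$tau_max,
                        mu_prior_mode = cfg$mu_prior_mode %||% "joint")
  list(spec = spec,
       chain = list(B = cfg$burnin %||% 5000L, N = cfg$N %||% 500L,
                    k = cfg$k %||% 500L, seed = cfg$seed))
}

#' Generate the package's synthetic reference datasets
#'
#' Writes the self-contained fixture set used by the simulation studies:
#' circular skew-von Mises samples at the two reference truths
#' `(mu, tau, gamma) = (2, 1, -1)` and `(3, 0.6, 1)` for
#' `n = 20, 50, 100, 500`, one spherical skew-FvML sample at
#' `mu = (1, 2), tau = 2, gamma = (1, -1)`, and one symmetric control
#' (`gamma = 0`). Regeneration under the same seed is byte-identical.
#'
#' @param out_dir writable directory (created if needed).
#' @param seed integer seed.
#' @return the manifest data.frame (`file`, `p`, `n`, `mu`, `tau`,
#'   `gamma`), also written to `manifest.csv`.
#' @export
generate_fixtures <- function(out_dir, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  truths <- list(list(mu = 2, tau = 1, gamma = -1),
                 list(mu = 3, tau = 0.6, gamma = 1))
  rows <- list()
  emit <- function(name, params, n) {
    s <- derive_seed(seed, name)
    x <- sample_sfvml(n, params, seed = s)
    write_directions(x, file.path(out_dir, paste0(name, ".csv")),
                     seed = s, config = params[c("mu", "tau", "gamma")])
    rows[[length(rows) + 1L]] <<- data.frame(
      file = paste0(name, ".csv"), p = params$p, n = n,
      mu = paste(params$mu, collapse = ";"), tau = params$tau,
      gamma = paste(params$gamma, collapse = ";"))
  }
  for (tr in truths) {
    pp <- sfvml_params(tr$mu, tr$tau, tr$gamma)
    for (n in c(20L, 50L, 100L, 500L)) {
      emit(sprintf("svm_mu%s_n%d", gsub("[.]", "p", format(tr$mu)), n), pp, n)
    }
  }
  emit("sfvml_p3_n100", sfvml_params(c(1, 2), 2, c(1, -1)), 100L)
  emit("svm_symmetric_n500", sfvml_params(3, 0.6, 0), 500L)
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
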