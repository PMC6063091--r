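#' Read a genotype matrix from delimited text
#'
#' Whitespace- or comma-delimited text, rows = individuals, columns = SNPs;
#' optional header row and leading sample-ID column.
#'
#' @param file path.
#' @param header file has a header row?
#' @param id_col first column holds sample IDs?
#' @param sep field separator; `""` (default) means any whitespace,
#'   autodetected as `","` when the first line contains commas.
#' @return Numeric matrix n x p.
#' @export
read_genotypes <- function(file, header = FALSE, id_col = FALSE, sep = "") {
  if (!file.exists(file)) stop(sprintf("genotype file not found: %s", file))
  if (identical(sep, "")) {
    first <- readLines(file, n = 1L)
    if (grepl(",", first, fixed = TRUE)) sep <- ","
  }
  df <- utils::read.table(file, header = header, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (id_col) df <- df[, -1L, drop = FALSE]
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (anyNA(m)) stop(sprintf("non-numeric or missing genotype entries in %s", file))
  dimnames(m) <- NULL
  m
}

#' Read a phenotype vector (one value per line)
#'
#' @param file path.
#' @return Numeric vector.
#' @export
read_phenotype <- function(file) {
  if (!file.exists(file)) stop(sprintf("phenotype file not found: %s", file))
  y <- scan(file, what = double(), quiet = TRUE)
  if (anyNA(y)) stop(sprintf("missing phenotype values in %s", file))
  y
}

#' Read and write spectrum files
#'
#' A spectrum file holds one nonnegative eigenvalue per line, preceded by a
#' two-line header `#n=<n>` and `#p=<p>`.
#'
#' @param file path.
#' @return For `read_spectrum`, a `grm_spectrum`.
#' @export
read_spectrum <- function(file) {
  if (!file.exists(file)) stop(sprintf("spectrum file not found: %s", file))
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  get_field <- function(key) {
    m <- grep(sprintf("^#%s=", key), hdr, value = TRUE)
    if (length(m) != 1L) stop(sprintf("spectrum file %s lacks a '#%s=' header line", file, key))
    as.integer(sub(sprintf("^#%s=", key), "", m))
  }
  n <- get_field("n")
  p <- get_field("p")
  vals <- as.numeric(lines[!grepl("^#", lines) & nzchar(trimws(lines))])
  if (length(vals) != n) {
    stop(sprintf("spectrum file %s declares n=%d but contains %d values", file, n, length(vals)))
  }
  spectrum_from_eigenvalues(vals, p = p)
}

#' @rdname read_spectrum
#' @param spec a `grm_spectrum`.
#' @export
write_spectrum <- function(spec, file) {
  writeLines(c(sprintf("#n=%d", spec$n), sprintf("#p=%d", spec$p),
               format(spec$t, digits = 15, scientific = FALSE, trim = TRUE)),
             file)
  invisible(file)
}

#' Write a JSON report
#'
#' Serializes a result list to JSON with stable key order and 12 significant
#' digits, tagged with a schema version and the package version.
#'
#' @param result named list.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_report <- function(result, path) {
  body <- c(list(schema = "gremlspectra-report/1",
                 package_version = as.character(utils::packageVersion("gremlspectra"))),
            result)
  jsonlite::write_json(body, path, auto_unbox = TRUE, digits = I(12), pretty = TRUE)
  invisible(path)
}

run_manifest <- function(command, params, seed) {
  list(command = command, params = params, seed = seed,
       package_version = as.character(utils::packageVersion("gremlspectra")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

fit_report <- function(fit) {
  list(psi_hat = fit$psi_hat, theta_hat = fit$theta_hat, phi_hat = fit$phi_hat,
       se_approx = fit$se_approx, bias_approx = fit$bias_approx,
       profile_loglik = fit$profile_loglik, score_at_opt = fit$score_at_opt,
       admissible_interval = c(fit$admissible$psi_min, 1),
       n_roots = fit$n_roots, converged = fit$converged, fallback = fit$fallback)
}

theory_report <- function(model, psi0, n, kmax, mu = NULL, beta = NULL,
                          alpha = NULL, gamma = NULL, spectrum_file = NULL) {
  tm <- switch(model,
    mp = mp_weight_moments(psi0, mu, kmax, n),
    paired = paired_moments(beta, psi0, kmax, n),
    dosage = dosage_moments(alpha, beta, mu, psi0, kmax, n),
    lognormal = lognormal_moments(gamma, psi0, kmax, n),
    empirical = tau_moments(read_spectrum(spectrum_file), psi0, kmax),
    stop(sprintf("unknown model '%s'", model))
  )
  if (model == "empirical") n <- tm$n
  list(model = model, psi0 = psi0, n = n,
       w_bar = tm$w_bar, tau = tm$tau, nu = 1 / sqrt(n * tm$tau[2L]),
       bias = bias_approx(tm, psi0, n),
       variance = variance_approx(tm, psi0, n),
       se = sqrt(variance_approx(tm, psi0, n)),
       bias_se_ratio = bias_se_ratio(tm, n))
}

parse_flags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop(sprintf("unexpected argument '%s'", a))
    key <- sub("^--", "", a)
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      out[[key]] <- TRUE
      i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  out
}

num_flag <- function(flags, name, default = NULL) {
  if (is.null(flags[[name]])) {
    if (is.null(default)) stop(sprintf("missing required flag --%s", name))
    return(default)
  }
  as.numeric(flags[[name]])
}

#' Command-line dispatch
#'
#' Entry point behind the `greml` CLI script: subcommands `fit`, `theory`,
#' `misspec` and `simulate`, each writing a JSON report plus a manifest that
#' records the full parameter set and seed needed to reproduce the run.
#' Returns (and, from the script, exits with) 0 on success, 2 on a
#' validation error, 1 on a computational failure.
#'
#' @param argv character vector of CLI arguments (subcommand first).
#' @return Integer exit code, invisibly; the report list is attached as
#'   attribute `report`.
#' @export
greml_dispatch <- function(argv) {
  res <- tryCatch({
    if (length(argv) < 1L) stop("usage: greml <fit|theory|misspec|simulate> [--flags]")
    cmd <- argv[1L]
    flags <- parse_flags(argv[-1L])
    out_path <- if (!is.null(flags$out)) flags$out else sprintf("greml-%s.json", cmd)
    seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else NULL
    if (!is.null(seed)) set.seed(seed)

    report <- switch(cmd,
      fit = {
        if (!is.null(flags$spectrum)) {
          spec <- read_spectrum(flags$spectrum)
          z <- read_phenotype(flags$rotated)
          if (length(z) != spec$n) stop("rotated vector length does not match spectrum n")
          fit_report(greml_fit(spec, rotated_data(z)))
        } else {
          raw <- read_genotypes(flags$genotypes,
                                header = isTRUE(flags$header),
                                id_col = isTRUE(flags[["id-col"]]))
          y <- read_phenotype(flags$phenotype)
          if (length(y) != nrow(raw)) stop("phenotype length does not match genotype rows")
          mode <- if (!is.null(flags$normalization)) flags$normalization else "global"
          fit_report(greml_fit_genotypes(raw, y, mode = mode))
        }
      },
      theory = theory_report(
        model = if (!is.null(flags$model)) flags$model else "mp",
        psi0 = num_flag(flags, "psi0"), n = num_flag(flags, "n"),
        kmax = as.integer(num_flag(flags, "kmax", 8)),
        mu = if (!is.null(flags$mu)) as.numeric(flags$mu) else NULL,
        beta = if (!is.null(flags$beta)) as.numeric(flags$beta) else NULL,
        alpha = if (!is.null(flags$alpha)) as.numeric(flags$alpha) else NULL,
        gamma = if (!is.null(flags$gamma)) as.numeric(flags$gamma) else NULL,
        spectrum_file = flags$spectrum),
      misspec = {
        sub <- flags$analysis
        if (is.null(sub)) stop("misspec requires --analysis {measurement-error|rcs|untagged}")
        switch(sub,
          "measurement-error" = phenotype_error_equiv(
            num_flag(flags, "psi"), num_flag(flags, "theta", 1),
            num_flag(flags, "sigma-m2")),
          rcs = {
            tm <- mp_weight_moments(num_flag(flags, "psi0"), num_flag(flags, "mu"),
                                    kmax = 8L, n = num_flag(flags, "n"))
            rcs_error_inflation(tm, k = num_flag(flags, "k"))
          },
          untagged = {
            tm <- mp_weight_moments(num_flag(flags, "psi0"), num_flag(flags, "mu"),
                                    kmax = 8L, n = num_flag(flags, "n"))
            untagged_bias(tm, k = num_flag(flags, "k"),
                          sigma_delta2 = num_flag(flags, "sigma-delta2", 0),
                          mean_sigma_l4 = num_flag(flags, "mean-sigma-l4", 1))
          },
          stop(sprintf("unknown misspec analysis '%s'", sub)))
      },
      simulate = {
        design <- sim_design(
          n = num_flag(flags, "n", 500), p = num_flag(flags, "p", 2000),
          psi0 = num_flag(flags, "psi0", 0.5), theta0 = num_flag(flags, "theta0", 1),
          k = as.integer(num_flag(flags, "k", num_flag(flags, "p", 2000))),
          n_causal_sets = as.integer(num_flag(flags, "sets", 50)),
          n_reps = as.integer(num_flag(flags, "reps", 100)),
          seed = if (is.null(seed)) 1L else seed)
        what <- if (!is.null(flags$what)) flags$what else "causal-study"
        switch(what,
          "causal-study" = {
            st <- causal_study(design)
            list(design = unclass(design),
                 var_between = st$decomposition$var_between,
                 var_between_se = st$decomposition$se_between,
                 var_within = st$decomposition$var_within,
                 theory_var_between = st$theory_var_between,
                 grand_mean_psi_hat = st$decomposition$grand_mean,
                 n_failed = st$n_failed)
          },
          stop(sprintf("unknown simulate target '%s'", what)))
      },
      stop(sprintf("unknown subcommand '%s'", cmd))
    )
    write_report(report, out_path)
    manifest <- run_manifest(cmd, flags, seed)
    jsonlite::write_json(manifest, paste0(out_path, ".manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    structure(0L, report = report)
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    code <- if (grepl("unknown|missing|usage|not found|does not match|outside|lacks",
                      conditionMessage(e))) 2L else 1L
    structure(code, report = NULL)
  })
  invisible(res)
}
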