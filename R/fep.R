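## Free energy perturbation over a coupling-parameter (lambda) ladder:
## per-window exponential (Zwanzig) averaging with log-sum-exp
## stabilisation, summed gas -> solvated, with a bootstrap uncertainty.

# Boltzmann constant in kJ mol^-1 K^-1; all energies are kJ/mol.
.kB <- 0.0083144621

#' Construct a FEP ladder
#'
#' @param lambda ordered coupling values in [0, 1], first 0 and last 1,
#'   strictly increasing.
#' @param windows list of length `length(lambda) - 1`; element i holds the
#'   energy-difference samples dU = U(lambda_{i+1}) - U(lambda_i) (kJ/mol)
#'   collected in window i.  Every window must be non-empty.
#' @param temperature K (> 0).
#' @return an object of class `"fep_ladder"`.
#' @export
fep_ladder <- function(lambda, windows, temperature = 298.15) {
  lambda <- as.numeric(lambda)
  if (length(lambda) < 2 || any(diff(lambda) <= 0))
    stop("lambda values must be strictly increasing (>= 2 of them)")
  if (abs(lambda[1]) > 1e-12 || abs(lambda[length(lambda)] - 1) > 1e-12)
    stop("lambda ladder must start at 0 and end at 1")
  if (length(windows) != length(lambda) - 1L)
    stop("need exactly one sample window per adjacent lambda pair")
  if (any(vapply(windows, length, integer(1)) == 0L))
    stop("every window must contain at least one dU sample")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(lambda = lambda, windows = windows,
                 temperature = temperature),
            class = "fep_ladder")
}

#' Zwanzig (exponential-averaging) free-energy increment for one window
#'
#' dG = -kB T ln < exp(-dU / kB T) >, evaluated with the log-sum-exp trick
#' so that large |dU| cannot overflow.
#'
#' @param samples dU samples, kJ/mol (finite, >= 1 of them).
#' @param temperature K.
#' @return window free energy, kJ/mol.
#' @export
zwanzig_increment <- function(samples, temperature = 298.15) {
  if (length(samples) < 1) stop("need at least one dU sample")
  if (any(!is.finite(samples))) stop("non-finite dU samples")
  if (temperature <= 0) stop("temperature must be positive")
  kt <- .kB * temperature
  z <- -samples / kt
  m <- max(z)
  -kt * (m + log(mean(exp(z - m))))
}

#' Accumulate a FEP ladder into a total solvation free energy
#'
#' Sums the per-window Zwanzig increments along the ladder (gas at
#' lambda = 0 to fully coupled at lambda = 1; negative totals mean
#' favourable solvation).  Uncertainty is the standard deviation of the
#' total over bootstrap resamples drawn within each window.
#'
#' @param ladder a [fep_ladder()].
#' @param n_boot bootstrap resamples (default 200).
#' @param seed RNG seed for the bootstrap.
#' @return an object of class `"fep_result"`: list with `per_window`
#'   (data frame: lambda_from, lambda_to, dg, n_samples), `dg_total`
#'   (exactly the sum of the window values), `uncertainty` (kJ/mol) and
#'   `temperature`.
#' @export
fep_total <- function(ladder, n_boot = 200, seed = 1L) {
  stopifnot(inherits(ladder, "fep_ladder"))
  nw <- length(ladder$windows)
  dg <- vapply(ladder$windows, zwanzig_increment, numeric(1),
               temperature = ladder$temperature)
  boot <- with_seed(seed, {
    tot <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      tot[b] <- sum(vapply(ladder$windows, function(w)
        zwanzig_increment(w[sample.int(length(w), replace = TRUE)],
                          ladder$temperature), numeric(1)))
    }
    tot
  })
  structure(list(
    per_window = data.frame(
      lambda_from = ladder$lambda[-(nw + 1L)],
      lambda_to = ladder$lambda[-1L],
      dg = dg,
      n_samples = vapply(ladder$windows, length, integer(1))),
    dg_total = sum(dg),
    uncertainty = stats::sd(boot),
    temperature = ladder$temperature), class = "fep_result")
}

#' @export
print.fep_result <- function(x, ...) {
  cat("FEP ladder:", nrow(x$per_window), "windows at", x$temperature, "K\n")
  cat(sprintf("  total dG = %.3f +/- %.3f kJ/mol\n",
              x$dg_total, x$uncertainty))
  invisible(x)
}

#' Read per-window dU sample files into a ladder
#'
#' Each file holds one window: a header line `# lambda <from> <to>`
#' followed by one dU value (kJ/mol) per line.  Files are ordered by their
#' `from` value.
#'
#' @param paths character vector of window file paths.
#' @param temperature K.
#' @return a [fep_ladder()].
#' @export
read_fep_windows <- function(paths, temperature = 298.15) {
  win <- lapply(paths, function(p) {
    lines <- readLines(p)
    hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(hdr) < 4 || hdr[2] != "lambda")
      stop("window file ", p, " lacks a '# lambda <from> <to>' header")
    list(from = as.numeric(hdr[3]), to = as.numeric(hdr[4]),
         du = as.numeric(lines[-1][nzchar(trimws(lines[-1]))]))
  })
  ord <- order(vapply(win, `[[`, numeric(1), "from"))
  win <- win[ord]
  lambda <- c(vapply(win, `[[`, numeric(1), "from"),
              win[[length(win)]]$to)
  fep_ladder(lambda, lapply(win, `[[`, "du"), temperature)
}

#' Write a ladder as per-window sample files
#'
#' @param ladder a [fep_ladder()].
#' @param dir output directory (created if needed).
#' @return invisibly, the file paths written.
#' @export
write_fep_windows <- function(ladder, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nw <- length(ladder$windows)
  paths <- file.path(dir, sprintf("window_%02d.dat", seq_len(nw)))
  for (i in seq_len(nw)) {
    con <- file(paths[i], "w")
    writeLines(sprintf("# lambda %.6f %.6f",
                       ladder$lambda[i], ladder$lambda[i + 1L]), con)
    writeLines(format(ladder$windows[[i]], digits = 10, trim = TRUE), con)
    close(con)
  }
  invisible(paths)
}

#' Write a FEP result table
#' @param result a `fep_result`.
#' @param path output TSV path.
#' @return invisibly, the data frame written.
#' @export
write_fep_report <- function(result, path) {
  df <- result$per_window
  df$dg <- round(df$dg, 4)
  df <- rbind(df, data.frame(lambda_from = 0, lambda_to = 1,
                             dg = round(result$dg_total, 4),
                             n_samples = sum(df$n_samples)))
  write_tsv_report(df, path,
                   sprintf("FEP per-window and total dG (kJ/mol), T = %g K; last row = total (uncertainty %.4f)",
                           result$temperature, result$uncertainty))
  invisible(df)
}
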