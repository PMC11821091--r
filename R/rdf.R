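## Radial distribution functions under periodic boundaries: site-site
## g(r) between two selections, and g(r) of target atoms measured from the
## per-frame micelle centre of mass.  Shell normalisation uses
## V_shell = (4 pi / 3) ((r + dr)^3 - r^3) and the bulk number density of
## the B selection.

new_rdf_result <- function(r, g, counts, bin_width, r_max, n_frames) {
  structure(list(r = r, g = g, counts = counts, bin_width = bin_width,
                 r_max = r_max, n_frames = n_frames), class = "rdf_result")
}

#' @export
print.rdf_result <- function(x, ...) {
  cat("RDF:", length(x$r), "bins of", x$bin_width, "nm up to", x$r_max,
      "nm,", x$n_frames, "frame(s)\n")
  pk <- which.max(x$g)
  cat(sprintf("  first maximum g = %.3f at r = %.3f nm\n", x$g[pk], x$r[pk]))
  invisible(x)
}

check_rdf_args <- function(box, bin_width, r_max) {
  if (is.null(box)) stop("RDFs under periodic boundaries require a box")
  if (is.null(r_max)) r_max <- min(box) / 2
  if (r_max > min(box) / 2 + 1e-9)
    stop("r_max (", r_max, " nm) exceeds half the smallest box edge (",
         min(box) / 2, " nm)")
  if (bin_width <= 0 || r_max <= bin_width) stop("bad bin width / r_max")
  r_max
}

shell_volumes <- function(edges) {
  4 * pi / 3 * diff(edges^3)
}

#' Site-site radial distribution function
#'
#' Histograms minimum-image A-B distances over all frames, excluding
#' self-pairs, and normalises each frame by N_A * rho_B * V_shell with
#' rho_B the bulk number density of the B selection.  When the two
#' selections share a species, intra-molecular pairs are excluded by
#' default so that self-interaction curves report inter-molecular
#' structure only.
#'
#' @param traj a [trajectory()].
#' @param sel_a,sel_b atom index vectors (1-based), non-empty.
#' @param bin_width histogram bin width, nm (default 0.002, fine enough to
#'   separate peaks 0.02 nm apart).
#' @param r_max histogram range, nm; defaults to half the smallest box
#'   edge and may not exceed it.
#' @param exclude_same_molecule drop pairs within one molecule; default
#'   (`NULL`) excludes them exactly when the selections share a species.
#' @return an `rdf_result`: bin centres `r` (nm), frame-averaged `g`, raw
#'   pair `counts` summed over frames, `bin_width`, `r_max`, `n_frames`.
#' @export
rdf_site_site <- function(traj, sel_a, sel_b, bin_width = 0.002,
                          r_max = NULL, exclude_same_molecule = NULL) {
  if (length(sel_a) < 1 || length(sel_b) < 1) stop("empty selection")
  topo <- traj$topology
  if (is.null(exclude_same_molecule)) {
    spa <- unique(topo$species[sel_a]); spb <- unique(topo$species[sel_b])
    exclude_same_molecule <- length(intersect(spa[!is.na(spa)],
                                              spb[!is.na(spb)])) > 0
  }
  box0 <- traj$frames[[1]]$box
  r_max <- check_rdf_args(box0, bin_width, r_max)
  nbins <- ceiling(r_max / bin_width - 1e-9)
  edges <- seq(0, by = bin_width, length.out = nbins + 1L)
  vshell <- shell_volumes(edges)
  g_acc <- numeric(nbins); counts <- numeric(nbins)
  for (fr in traj$frames) {
    if (is.null(fr$box)) stop("frame without a box in periodic RDF")
    cts <- .pair_hist_pbc(fr$coords[sel_a, , drop = FALSE],
                          fr$coords[sel_b, , drop = FALSE],
                          fr$box, bin_width, r_max,
                          as.integer(sel_a), as.integer(sel_b),
                          as.integer(topo$residue_id[sel_a]),
                          as.integer(topo$residue_id[sel_b]),
                          isTRUE(exclude_same_molecule))
    vol <- prod(fr$box)
    rho_b <- length(sel_b) / vol
    g_acc <- g_acc + cts / (length(sel_a) * rho_b * vshell)
    counts <- counts + cts
  }
  nf <- n_frames(traj)
  new_rdf_result(r = edges[-1] - bin_width / 2, g = g_acc / nf,
                 counts = counts, bin_width = bin_width, r_max = r_max,
                 n_frames = nf)
}

#' Radial distribution from the micelle centre of mass
#'
#' For each frame computes the micelle COM (PBC-whole, mass-weighted) and
#' histograms the minimum-image distances from that single point to every
#' target atom; normalisation uses the bulk number density of the target
#' selection (the COM counts as N_A = 1).
#'
#' @param traj a [trajectory()].
#' @param micelle_sel atom indices defining the micelle.
#' @param target_sel atom indices whose radial distribution is measured.
#' @inheritParams rdf_site_site
#' @return an `rdf_result`.
#' @export
rdf_from_com <- function(traj, micelle_sel, target_sel, bin_width = 0.002,
                         r_max = NULL) {
  if (length(micelle_sel) < 1 || length(target_sel) < 1)
    stop("empty selection")
  box0 <- traj$frames[[1]]$box
  r_max <- check_rdf_args(box0, bin_width, r_max)
  nbins <- ceiling(r_max / bin_width - 1e-9)
  edges <- seq(0, by = bin_width, length.out = nbins + 1L)
  vshell <- shell_volumes(edges)
  masses <- traj$topology$mass
  g_acc <- numeric(nbins); counts <- numeric(nbins)
  for (fr in traj$frames) {
    com <- micelle_com(fr, micelle_sel, masses)
    d <- minimum_image(com, fr$coords[target_sel, , drop = FALSE], fr$box)
    r <- sqrt(rowSums(rbind_coords(d)^2))
    r <- r[r > 0 & r <= r_max + 1e-12]
    bins <- pmin(nbins, floor(r / bin_width) + 1L)
    cts <- tabulate(bins, nbins)
    rho <- length(target_sel) / prod(fr$box)
    g_acc <- g_acc + cts / (rho * vshell)
    counts <- counts + cts
  }
  nf <- n_frames(traj)
  new_rdf_result(r = edges[-1] - bin_width / 2, g = g_acc / nf,
                 counts = counts, bin_width = bin_width, r_max = r_max,
                 n_frames = nf)
}

#' Write RDF curves as text
#'
#' One curve gives a two-column `r g` file; several curves (a named list)
#' give a multi-column TSV whose header names each site pair.
#'
#' @param rdf an `rdf_result` or named list of them (equal binning).
#' @param path output path.
#' @return invisibly, the data frame written.
#' @export
write_rdf <- function(rdf, path) {
  if (inherits(rdf, "rdf_result")) rdf <- list(g = rdf)
  r <- rdf[[1]]$r
  for (x in rdf)
    if (!isTRUE(all.equal(x$r, r)))
      stop("all curves must share the same bins to be written together")
  df <- data.frame(r = r)
  for (nm in names(rdf)) df[[nm]] <- round(rdf[[nm]]$g, 6)
  write_tsv_report(df, path, "radial distribution functions; r in nm")
  invisible(df)
}
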