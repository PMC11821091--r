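## Geometric hydrogen-bond detection (Luzar-Chandler criterion: donor-
## acceptor distance and hydrogen-donor-acceptor angle, both inclusive)
## and the species-pair classification table with grouped shares.

.hbond_categories <- c("Surf-Surf", "Surf-Ch", "Surf-HBD", "Surf-Cl",
                       "Ch-Ch", "Ch-HBD", "Ch-Cl", "Cl-HBD", "HBD-HBD",
                       "other")
.surf_categories <- c("Surf-Surf", "Surf-Ch", "Surf-HBD", "Surf-Cl")
.des_categories <- c("Ch-Ch", "Ch-HBD", "Ch-Cl", "Cl-HBD", "HBD-HBD")

#' Hydrogen-bond criterion
#'
#' @param r_da_max maximum donor-acceptor distance, nm (default 0.35).
#' @param angle_max maximum hydrogen-donor-acceptor angle at the donor,
#'   degrees (default 30).  Both cutoffs are inclusive.
#' @return an object of class `"hbond_criterion"`.
#' @export
hbond_criterion <- function(r_da_max = 0.35, angle_max = 30) {
  if (r_da_max <= 0 || angle_max <= 0) stop("cutoffs must be positive")
  structure(list(r_da_max = r_da_max, angle_max = angle_max),
            class = "hbond_criterion")
}

#' Detect hydrogen bonds in one frame
#'
#' Emits every (donor heavy, hydrogen, acceptor) triplet whose
#' minimum-image donor-acceptor distance is at most `r_da_max` and whose
#' angle at the donor between donor->hydrogen and donor->acceptor is at
#' most `angle_max` (both inclusive).  The donor atom itself is never its
#' own acceptor; donor-acceptor pairs within one molecule are skipped
#' unless `include_intra = TRUE`.
#'
#' @param frame an `md_frame` with a box.
#' @param donors two-column integer matrix (or data frame) of (heavy,
#'   hydrogen) atom indices, 1-based.
#' @param acceptors integer vector of acceptor atom indices.
#' @param molecule_id residue_id per atom (e.g. `topology$residue_id`).
#' @param criterion an [hbond_criterion()].
#' @param include_intra also count donor-acceptor pairs within one
#'   molecule.
#' @return integer matrix with columns `donor`, `hydrogen`, `acceptor`,
#'   one row per detected bond.
#' @export
detect_hbonds_frame <- function(frame, donors, acceptors, molecule_id,
                                criterion = hbond_criterion(),
                                include_intra = FALSE) {
  donors <- as.matrix(donors)
  if (ncol(donors) != 2) stop("donors must be (heavy, hydrogen) pairs")
  if (is.null(frame$box)) stop("hydrogen-bond detection requires a box")
  if (nrow(donors) > 0) {
    dh <- minimum_image(frame$coords[donors[, 1], , drop = FALSE],
                        frame$coords[donors[, 2], , drop = FALSE], frame$box)
    dlen <- sqrt(rowSums(rbind_coords(dh)^2))
    far <- which(dlen > 0.15)
    for (i in far)
      warning("hydrogen ", donors[i, 2], " is ", round(dlen[i], 3),
              " nm from its donor heavy atom ", donors[i, 1],
              " (> 0.15 nm): check the donor pairing", call. = FALSE)
  }
  if (nrow(donors) == 0 || length(acceptors) == 0)
    return(matrix(integer(0), 0, 3,
                  dimnames = list(NULL, c("donor", "hydrogen", "acceptor"))))
  res <- .hbond_detect(frame$coords, frame$box,
                       as.integer(donors[, 1]), as.integer(donors[, 2]),
                       as.integer(acceptors), as.integer(molecule_id),
                       criterion$r_da_max, criterion$angle_max,
                       isTRUE(include_intra))
  colnames(res) <- c("donor", "hydrogen", "acceptor")
  res
}

#' Derive donor pairs and acceptors from topology site roles
#'
#' Donors are (donor_heavy, donor_hydrogen) pairs: every atom with role
#' `donor_hydrogen` is paired with the nearest preceding `donor_heavy`
#' atom of the same molecule (or the molecule's first, when the hydrogen
#' is listed before any heavy atom).  Acceptors are all atoms with role
#' `acceptor`.
#'
#' @param topology a topology data frame with site roles assigned.
#' @return list with `donors` (2-column matrix) and `acceptors` (integer
#'   vector).
#' @export
hbond_participants <- function(topology) {
  hyd <- which(topology$site_role == "donor_hydrogen")
  heavy <- which(topology$site_role == "donor_heavy")
  acceptors <- which(topology$site_role == "acceptor")
  donors <- matrix(integer(0), 0, 2)
  if (length(hyd)) {
    donors <- t(vapply(hyd, function(h) {
      cand <- heavy[topology$residue_id[heavy] == topology$residue_id[h]]
      if (!length(cand))
        stop("molecule with residue_id ", topology$residue_id[h],
             " has a donor_hydrogen but no donor_heavy atom")
      before <- cand[cand < h]
      c(if (length(before)) max(before) else cand[1], h)
    }, integer(2)))
  }
  list(donors = donors, acceptors = acceptors)
}

# Unordered species pair -> category label; anything outside the standard
# set (counter-ions, unassigned species) falls into "other".
species_pair_category <- function(sp_a, sp_b) {
  lv <- c("Surf", "Ch", "Cl", "HBD", "CounterIon", "Other")
  ia <- match(sp_a, lv); ib <- match(sp_b, lv)
  lo <- pmin(ia, ib); hi <- pmax(ia, ib)
  lab <- paste(lv[lo], lv[hi], sep = "-")
  lab[is.na(lo) | is.na(hi)] <- "other"
  ifelse(lab %in% .hbond_categories, lab, "other")
}

#' Hydrogen-bond classification table over a trajectory
#'
#' Detects bonds frame by frame (species and site roles must be assigned,
#' e.g. via [assign_species()]) and bins them by the unordered species
#' pair of the donor heavy atom and the acceptor, in the conventional
#' category order Surf-Surf, Surf-Ch, Surf-HBD, Surf-Cl, Ch-Ch, Ch-HBD,
#' Ch-Cl, Cl-HBD, HBD-HBD, other.  Reports the per-category mean count
#' over frames with its SD, the percentage of the total, and the grouped
#' surfactant-involving vs DES-only shares.
#'
#' @param traj a [trajectory()] with species and site roles assigned.
#' @param criterion an [hbond_criterion()].
#' @param include_intra count intra-molecular donor-acceptor pairs too.
#' @return an object of class `"hbond_table"`: `categories` (data frame:
#'   category, mean, sd, percent), `total_mean`, `shares` (list:
#'   surfactant, des_only; `NA` and `flagged` when no bonds at all),
#'   `n_frames`, `criterion`.
#' @export
hbond_table <- function(traj, criterion = hbond_criterion(),
                        include_intra = FALSE) {
  topo <- traj$topology
  parts <- hbond_participants(topo)
  if (nrow(parts$donors) == 0 || length(parts$acceptors) == 0)
    warning("no donors or no acceptors in the topology: empty table",
            call. = FALSE)
  nf <- n_frames(traj)
  per_frame <- matrix(0, nf, length(.hbond_categories),
                      dimnames = list(NULL, .hbond_categories))
  for (f in seq_len(nf)) {
    bonds <- detect_hbonds_frame(traj$frames[[f]], parts$donors,
                                 parts$acceptors, topo$residue_id,
                                 criterion, include_intra)
    if (nrow(bonds)) {
      cat_f <- species_pair_category(topo$species[bonds[, "donor"]],
                                     topo$species[bonds[, "acceptor"]])
      tb <- table(factor(cat_f, levels = .hbond_categories))
      per_frame[f, ] <- as.numeric(tb)
    }
  }
  means <- colMeans(per_frame)
  sds <- apply(per_frame, 2, stats::sd)
  total <- sum(means)
  cats <- data.frame(category = .hbond_categories,
                     mean = unname(means), sd = unname(sds),
                     percent = if (total > 0) unname(means) / total * 100
                               else rep(NA_real_, length(means)),
                     stringsAsFactors = FALSE)
  shares <- if (total > 0) {
    c(aggregate_shares(means, total), list(flagged = FALSE))
  } else {
    list(surfactant = NA_real_, des_only = NA_real_, flagged = TRUE)
  }
  structure(list(categories = cats, total_mean = total, shares = shares,
                 n_frames = nf, criterion = criterion),
            class = "hbond_table")
}

#' Grouped hydrogen-bond shares
#'
#' Surfactant-involving share = (Surf-Surf + Surf-Ch + Surf-HBD +
#' Surf-Cl) / total * 100; DES-only share = (Ch-Ch + Ch-HBD + Ch-Cl +
#' Cl-HBD + HBD-HBD) / total * 100.
#'
#' @param counts named per-category mean counts (names from the standard
#'   category set).
#' @param total total bond count (> 0).
#' @return list with `surfactant` and `des_only` percentages.
#' @export
aggregate_shares <- function(counts, total) {
  if (total <= 0) stop("total bond count must be positive")
  cn <- names(counts)
  if (is.null(cn)) stop("counts must be named by category")
  surf <- sum(counts[cn %in% .surf_categories])
  des <- sum(counts[cn %in% .des_categories])
  list(surfactant = surf / total * 100, des_only = des / total * 100)
}

#' Percent change between two totals
#'
#' `(b / a - 1) * 100`: the relative growth from `a` to `b`, e.g. of the
#' surfactant-involving bond count between two micelle sizes.
#'
#' @param a baseline value (non-zero).
#' @param b comparison value.
#' @return percent change.
#' @export
percent_change <- function(a, b) {
  if (a == 0) stop("baseline must be non-zero")
  (b / a - 1) * 100
}

#' @export
print.hbond_table <- function(x, ...) {
  cat("hydrogen bonds over", x$n_frames, "frame(s), criterion",
      x$criterion$r_da_max, "nm /", x$criterion$angle_max, "deg\n")
  df <- x$categories
  df$mean <- round(df$mean, 1); df$sd <- round(df$sd, 1)
  df$percent <- round(df$percent, 1)
  print(df, row.names = FALSE)
  if (!isTRUE(x$shares$flagged))
    cat(sprintf("  surfactant-involving %.1f%% / DES-only %.1f%%\n",
                x$shares$surfactant, x$shares$des_only))
  else cat("  no bonds detected: shares undefined\n")
  invisible(x)
}

#' Write an H-bond table in the conventional column order
#'
#' @param tables named list of `hbond_table` objects (names = system
#'   labels).
#' @param path output TSV path.
#' @return invisibly, the data frame written.
#' @export
write_hbond_report <- function(tables, path) {
  rows <- lapply(names(tables), function(nm) {
    tb <- tables[[nm]]
    m <- stats::setNames(tb$categories$mean, tb$categories$category)
    s <- stats::setNames(tb$categories$sd, tb$categories$category)
    p <- stats::setNames(tb$categories$percent, tb$categories$category)
    core <- .hbond_categories[.hbond_categories != "other"]
    data.frame(system = nm,
               t(stats::setNames(sprintf("%.1f (%.1f)", m[core], s[core]),
                                 core)),
               total = round(tb$total_mean, 1),
               surf_share_pct = round(tb$shares$surfactant, 1),
               des_share_pct = round(tb$shares$des_only, 1),
               t(stats::setNames(round(p[core], 1), paste0(core, "_pct"))),
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write_tsv_report(df, path,
                   "mean hydrogen-bond counts per species pair (SD), shares in %")
  invisible(df)
}
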