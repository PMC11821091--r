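## Species map: configuration that assigns each (residue_name, atom_name)
## key a species category and optional site role / mass override.  Stored as
## a plain data frame of rules; YAML is the on-disk form.

.species_levels <- c("Surf", "Ch", "Cl", "HBD", "CounterIon", "Other")
.site_roles <- c("head", "tail", "bend_center", "donor_heavy",
                 "donor_hydrogen", "acceptor", "none")

#' Construct a species map
#'
#' @param rules data frame with columns `residue_name`, `atom_name`,
#'   `species` and optionally `site_role` and `mass`.  `atom_name = "*"`
#'   matches every atom of the residue not covered by a more specific rule.
#' @return an object of class `"species_map"`.
#' @export
species_map <- function(rules) {
  rules <- as.data.frame(rules, stringsAsFactors = FALSE)
  need <- c("residue_name", "atom_name", "species")
  if (!all(need %in% names(rules)))
    stop("species map rules need columns: ", paste(need, collapse = ", "))
  if (is.null(rules$site_role)) rules$site_role <- "none"
  rules$site_role[is.na(rules$site_role)] <- "none"
  if (is.null(rules$mass)) rules$mass <- NA_real_
  bad <- setdiff(unique(rules$species), .species_levels)
  if (length(bad))
    stop("unknown species categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "))
  bad <- setdiff(unique(rules$site_role), .site_roles)
  if (length(bad))
    stop("unknown site role(s): ", paste(bad, collapse = ", "))
  key <- paste(rules$residue_name, rules$atom_name, sep = "/")
  dup <- duplicated(key)
  if (any(dup)) {
    conflict <- key[dup][!vapply(which(dup), function(i) {
      j <- match(key[i], key)
      identical(rules$species[i], rules$species[j]) &&
        identical(rules$site_role[i], rules$site_role[j])
    }, logical(1))]
    if (length(conflict))
      stop("conflicting species-map rules for key(s): ",
           paste(unique(conflict), collapse = ", "))
    rules <- rules[!dup, , drop = FALSE]
  }
  structure(list(rules = rules), class = "species_map")
}

#' Read a species map from a YAML file
#'
#' Layout: top-level `residues`, one entry per residue name, each with an
#' `atoms` mapping of atom name to `{species, site_role, mass}` (the last
#' two optional).  A `"*"` atom entry is a residue-wide default.
#'
#' @param path YAML file path.
#' @return a [species_map()].
#' @export
read_species_map <- function(path) {
  if (!file.exists(path)) stop("no such species map file: ", path)
  y <- yaml::read_yaml(path)
  if (is.null(y$residues)) stop("species map YAML needs a 'residues' section")
  rows <- list()
  for (res in names(y$residues)) {
    atoms <- y$residues[[res]]$atoms
    if (is.null(atoms)) stop("residue '", res, "' has no 'atoms' section")
    for (an in names(atoms)) {
      a <- atoms[[an]]
      rows[[length(rows) + 1L]] <- data.frame(
        residue_name = res, atom_name = an,
        species = a$species %||% stop("atom ", res, "/", an, " lacks species"),
        site_role = a$site_role %||% "none",
        mass = a$mass %||% NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  species_map(do.call(rbind, rows))
}

#' Write a species map to YAML
#' @param map a [species_map()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_species_map <- function(map, path) {
  out <- list(residues = list())
  for (res in unique(map$rules$residue_name)) {
    sub <- map$rules[map$rules$residue_name == res, , drop = FALSE]
    atoms <- list()
    for (i in seq_len(nrow(sub))) {
      e <- list(species = sub$species[i])
      if (sub$site_role[i] != "none") e$site_role <- sub$site_role[i]
      if (!is.na(sub$mass[i])) e$mass <- sub$mass[i]
      atoms[[sub$atom_name[i]]] <- e
    }
    out$residues[[res]] <- list(atoms = atoms)
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign species categories and site roles to a trajectory
#'
#' Looks every atom up by (residue_name, atom_name), falling back to the
#' residue's `"*"` rule.  In strict mode (default) any unmapped atom is a
#' configuration error listing the offending keys; with
#' `permissive = TRUE` unmapped atoms become species `"Other"`.
#'
#' @param traj a [trajectory()].
#' @param map a [species_map()].
#' @param permissive allow unmapped atoms (labelled `Other`).
#' @return the trajectory with `species`, `site_role` (and any mass
#'   overrides) filled in.
#' @export
assign_species <- function(traj, map, permissive = FALSE) {
  stopifnot(inherits(map, "species_map"))
  topo <- traj$topology
  rules <- map$rules
  key <- paste(topo$residue_name, topo$atom_name, sep = "/")
  rkey <- paste(rules$residue_name, rules$atom_name, sep = "/")
  hit <- match(key, rkey)
  fallback <- match(paste(topo$residue_name, "*", sep = "/"), rkey)
  hit[is.na(hit)] <- fallback[is.na(hit)]
  if (anyNA(hit) && !permissive) {
    missing_keys <- sort(unique(key[is.na(hit)]))
    stop("species map does not cover atom key(s): ",
         paste(missing_keys, collapse = ", "),
         " (set permissive = TRUE to label them Other)")
  }
  topo$species <- ifelse(is.na(hit), "Other", rules$species[hit])
  topo$site_role <- ifelse(is.na(hit), "none", rules$site_role[hit])
  override <- !is.na(hit) & !is.na(rules$mass[hit])
  topo$mass[override] <- rules$mass[hit[override]]
  traj$topology <- topo
  traj
}

#' Select atom indices by topology predicate
#'
#' Convenience selector over the topology columns; all given filters are
#' ANDed.  Returns 1-based indices into the coordinate rows.
#'
#' @param traj a [trajectory()].
#' @param species,site_role,atom_name,residue_name optional values to match.
#' @return integer vector of atom indices (1-based).
#' @export
select_atoms <- function(traj, species = NULL, site_role = NULL,
                         atom_name = NULL, residue_name = NULL) {
  t <- traj$topology
  keep <- rep(TRUE, nrow(t))
  if (!is.null(species)) keep <- keep & t$species %in% species
  if (!is.null(site_role)) keep <- keep & t$site_role %in% site_role
  if (!is.null(atom_name)) keep <- keep & t$atom_name %in% atom_name
  if (!is.null(residue_name)) keep <- keep & t$residue_name %in% residue_name
  which(keep)
}
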