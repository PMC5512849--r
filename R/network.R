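#' Load a metabolic network from a YAML description
#'
#' Reads a structured network file describing species (with compartment and
#' carbon count), reactions (stoichiometry plus a declared rate-law form),
#' the transcription-factor regulation edge table, and the conserved cofactor
#' pools.  The file schema is documented in the shipped
#' `extdata/ecoli_core.yaml`.
#'
#' Compartments: `extracellular` species are tracked in g/l (field `mw`
#' converts from mmol), `cytoplasm` species in mmol/gDW and subject to growth
#' dilution, `pool` species are the tracked member of a conserved pair (the
#' partner concentration is `total - tracked`), and `boundary` species
#' (CO2, O2) carry no differential state.
#'
#' @param path path to a YAML network file.
#' @return an object of class `metabolic_network`.
#' @seealso [ecoli_network()], [validate_network()]
#' @export
load_network <- function(path) {
  raw <- yaml::read_yaml(path)
  net <- structure(list(
    name       = raw$name %||% "network",
    species    = raw$species,
    reactions  = raw$reactions,
    regulation = raw$regulation %||% list(),
    biomass    = raw$biomass %||% NULL
  ), class = "metabolic_network")
  net$species_ids  <- vapply(net$species, `[[`, "", "id")
  net$reaction_ids <- vapply(net$reactions, `[[`, "", "id")
  names(net$species)   <- net$species_ids
  names(net$reactions) <- net$reaction_ids
  rep <- validate_network(net)
  if (length(rep$violations) > 0L)
    warning("network has structural violations: ",
            paste(rep$violations, collapse = "; "))
  net
}

#' The shipped E. coli central-carbon network
#'
#' Convenience accessor for the curated network distributed with the package:
#' glycolysis, pentose-phosphate, TCA, glyoxylate, anaplerotic and
#' fermentative pathways, the respiratory chain (Nuo, Ndh, Cyo, Cyd) coupled
#' to a conserved quinone pool, and the Fnr/ArcA regulation edge table.
#'
#' @return a `metabolic_network`.
#' @export
ecoli_network <- function() {
  load_network(system.file("extdata", "ecoli_core.yaml",
                           package = "redoxferm", mustWork = TRUE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stoichiometric matrix of a network
#'
#' @param network a `metabolic_network`.
#' @return species x reactions numeric matrix (all declared species,
#'   including boundary species and pool partners).
#' @export
stoichiometry_matrix <- function(network) {
  sp <- network$species_ids
  partners <- unlist(lapply(network$species, function(s) s$partner), use.names = FALSE)
  rows <- c(sp, partners)
  S <- matrix(0, nrow = length(rows), ncol = length(network$reactions),
              dimnames = list(rows, network$reaction_ids))
  for (j in seq_along(network$reactions)) {
    st <- network$reactions[[j]]$stoichiometry
    S[names(st), j] <- unlist(st)
  }
  S
}

#' Validate a metabolic network
#'
#' Checks structural invariants: every reaction references declared species;
#' the canonical enzyme set of the central-carbon network is present; each
#' conserved pool has zero stoichiometric row sum (pool member + partner) in
#' every reaction; every reaction is carbon balanced on the declared
#' per-species carbon counts; every regulation edge points at a declared
#' reaction.  Failures are collected into a machine-readable report, not
#' raised one at a time.
#'
#' @param network a `metabolic_network`.
#' @param require_canonical if `TRUE` (default) the canonical enzyme list is
#'   enforced; set `FALSE` for toy networks.
#' @return a list with elements `ok` (logical) and `violations` (character).
#' @export
validate_network <- function(network, require_canonical = NULL) {
  v <- character(0)
  sp_ids <- network$species_ids
  partners <- unlist(lapply(network$species, function(s) s$partner), use.names = FALSE)
  known <- c(sp_ids, partners)
  if (is.null(require_canonical))
    require_canonical <- identical(network$name, "ecoli_core_redox")

  for (rx in network$reactions) {
    st <- rx$stoichiometry
    bad <- setdiff(names(st), known)
    if (length(bad) > 0L)
      v <- c(v, sprintf("reaction %s references undeclared species: %s",
                        rx$id, paste(bad, collapse = ",")))
  }

  if (require_canonical) {
    needed <- c("PTS", "Glk", "Pfk", "Fba", "L_Emp", "Pyk", "Pps", "PDH",
                "Pfl", "LDH", "ALDH", "ADH", "PTACK", "Acs", "CS", "ICDH",
                "aKGDH", "SDH", "Frd", "Fum", "MDH", "Mez", "Pck", "Ppc",
                "Icl", "MS", "G6PDH", "PGDH", "Rpe", "Rpi", "TktA", "TktB",
                "Tal", "Fbp", "Nuo", "Ndh", "Cyo", "Cyd", "npts")
    missing <- setdiff(needed, network$reaction_ids)
    for (m in missing) v <- c(v, sprintf("missing canonical reaction %s", m))
  }

  # conserved pools: member + partner row sums must vanish reaction-wise
  for (s in network$species) {
    if (identical(s$compartment, "pool")) {
      for (rx in network$reactions) {
        st <- rx$stoichiometry
        rs <- (st[[s$id]] %||% 0) + (st[[s$partner]] %||% 0)
        if (abs(rs) > 1e-12)
          v <- c(v, sprintf("pool %s has nonzero row sum %g in reaction %s",
                            s$pool, rs, rx$id))
      }
    }
  }

  carbon <- vapply(network$species, function(s) as.numeric(s$carbon %||% 0), 0)
  names(carbon) <- sp_ids
  for (p in partners) carbon[p] <- 0  # pool partners are carbon-free cofactors
  for (rx in network$reactions) {
    st <- rx$stoichiometry
    cb <- sum(unlist(st) * carbon[names(st)], na.rm = TRUE)
    if (is.finite(cb) && abs(cb) > 1e-9)
      v <- c(v, sprintf("reaction %s is not carbon balanced (net %g C)", rx$id, cb))
  }

  for (e in network$regulation) {
    if (!(e$reaction %in% network$reaction_ids))
      v <- c(v, sprintf("regulation edge %s->%s targets unknown reaction %s",
                        e$tf, e$gene, e$reaction))
    if (!(e$tf %in% c("Fnr", "ArcA")))
      v <- c(v, sprintf("unknown transcription factor %s", e$tf))
    if (!(e$sign %in% c("activation", "repression")))
      v <- c(v, sprintf("edge %s->%s has unknown sign %s", e$tf, e$gene, e$sign))
  }

  list(ok = length(v) == 0L, violations = v)
}

#' @export
print.metabolic_network <- function(x, ...) {
  cat(sprintf("<metabolic_network> %s\n", x$name))
  comp <- table(vapply(x$species, `[[`, "", "compartment"))
  cat(sprintf("  %d species (%s)\n", length(x$species),
              paste(sprintf("%s: %d", names(comp), comp), collapse = ", ")))
  cat(sprintf("  %d reactions, %d regulation edges\n",
              length(x$reactions), length(x$regulation)))
  invisible(x)
}
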