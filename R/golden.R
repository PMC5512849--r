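# Golden regression: canonical strain x DO runs summarized and stamped with
# the parameter digest.  The shipped table is regenerated only by an
# explicit call to golden_regression(write = TRUE); comparisons never
# regenerate it silently.

#' Compute (or regenerate) the golden regression table
#'
#' Runs the canonical batches (WT and the fnr/arcA/pfl knockouts at DO 0,
#' 1, 3, 8 and 40 percent), and summarizes products at depletion, depletion
#' time and final biomass.  The table carries the parameter digest so a
#' mismatch against the shipped table distinguishes "parameters changed"
#' from "behavior changed".
#'
#' @param strains character vector of strain shortcuts.
#' @param do_levels DO percentages.
#' @param network,params model definition.
#' @param write if `TRUE`, overwrite the shipped golden table (development
#'   use only).
#' @param ... passed to [simulate_batch()].
#' @return data frame with attribute `digest`.
#' @export
golden_regression <- function(strains = c("WT", "fnr", "arcA", "pfl"),
                              do_levels = c(0, 1, 3, 8, 40),
                              network = ecoli_network(),
                              params = default_parameters(),
                              write = FALSE, ...) {
  rows <- list()
  for (s in strains) for (do in do_levels) {
    pr <- cultivation_protocol(do = do, strain = s)
    traj <- simulate_batch(pr, network = network, params = params, ...)
    p <- if (traj$depleted) products_at_depletion(traj) else
      stats::setNames(rep(NA_real_, 7),
                      c("acetate", "lactate", "formate", "ethanol",
                        "succinate", "t_dep", "X"))
    rows[[length(rows) + 1L]] <- data.frame(
      strain = s, DO_percent = do, depleted = traj$depleted,
      acetate = p[["acetate"]], lactate = p[["lactate"]],
      formate = p[["formate"]], ethanol = p[["ethanol"]],
      succinate = p[["succinate"]], t_dep = p[["t_dep"]], X = p[["X"]])
  }
  out <- do.call(rbind, rows)
  attr(out, "digest") <- parameter_digest(params)
  if (write) {
    path <- file.path("inst", "extdata", "golden_summary.csv")
    tab <- out
    num <- vapply(tab, is.numeric, TRUE)
    tab[num] <- lapply(tab[num], function(x) sprintf("%.12g", x))
    tab$digest <- attr(out, "digest")
    utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  }
  out
}

#' Load the shipped golden regression table
#'
#' @return data frame with attribute `digest` (the parameter digest the
#'   table was generated under).
#' @export
golden_reference <- function() {
  path <- system.file("extdata", "golden_summary.csv",
                      package = "redoxferm", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  dg <- unique(trimws(tab$digest))
  tab$digest <- NULL
  for (col in setdiff(names(tab), c("strain", "depleted")))
    tab[[col]] <- as.numeric(tab[[col]])
  tab$depleted <- as.logical(trimws(tab$depleted))
  attr(tab, "digest") <- dg
  tab
}

#' Compare freshly computed rows against the golden table
#'
#' @param current data frame in the layout of [golden_regression()].
#' @param reference golden table (default: the shipped one).
#' @param tol relative tolerance.
#' @return list with `ok` and a data frame `diff` of offending cells.
#' @export
compare_golden <- function(current, reference = golden_reference(),
                           tol = 1e-6) {
  key <- c("strain", "DO_percent")
  num_cols <- c("acetate", "lactate", "formate", "ethanol", "succinate",
                "t_dep", "X")
  merged <- merge(current, reference, by = key, suffixes = c("", ".ref"))
  diffs <- list()
  for (col in num_cols) {
    a <- merged[[col]]; b <- merged[[paste0(col, ".ref")]]
    rel <- abs(a - b) / pmax(abs(b), 1e-8)
    bad <- which(is.na(rel) | rel > tol)
    for (i in bad)
      diffs[[length(diffs) + 1L]] <- data.frame(
        strain = merged$strain[i], DO_percent = merged$DO_percent[i],
        column = col, current = a[i], reference = b[i], rel_diff = rel[i])
  }
  diff <- if (length(diffs) > 0L) do.call(rbind, diffs) else
    data.frame(strain = character(0), DO_percent = numeric(0),
               column = character(0), current = numeric(0),
               reference = numeric(0), rel_diff = numeric(0))
  list(ok = nrow(diff) == 0L, diff = diff)
}
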