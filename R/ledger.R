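#' Electron-carrier and energy ledger
#'
#' A `carrier_ledger` is the bookkeeping unit of the bioenergetics engine: a
#' signed tally, per mol of substrate, of reduced electron carriers, ATP from
#' substrate-level phosphorylation, translocated protons, and the small
#' molecules (ammonia, CO2) whose release the study tracks. Reduced ferredoxin
#' is counted in electron *pairs* (2 Fd_rd = 1 pair) so that one unit of any
#' carrier field always carries two electrons.
#'
#' Ledgers form an additive group: they add component-wise and the zero ledger
#' is the identity, so the net ledger of a pathway is the flux-weighted sum of
#' its step ledgers.
#'
#' @param fd_rd_pairs electron pairs held as reduced ferredoxin.
#' @param nadh mol NADH per mol substrate.
#' @param nadph mol NADPH per mol substrate.
#' @param atp mol ATP from substrate-level phosphorylation (ATP -> AMP + PPi
#'   steps count as 2 ATP equivalents).
#' @param protons protons translocated outward; negative values consume the
#'   gradient.
#' @param nh3 mol ammonia released.
#' @param co2 mol CO2 released (negative = fixed).
#' @return An object of class `carrier_ledger` (a named numeric vector).
#' @examples
#' carrier_ledger(nadh = 2, atp = 2)  # glycolysis of one fructose
#' @export
carrier_ledger <- function(fd_rd_pairs = 0, nadh = 0, nadph = 0, atp = 0,
                           protons = 0, nh3 = 0, co2 = 0) {
  x <- c(fd_rd_pairs = fd_rd_pairs, nadh = nadh, nadph = nadph, atp = atp,
         protons = protons, nh3 = nh3, co2 = co2)
  stopifnot(is.numeric(x), length(x) == 7L, !anyNA(x))
  structure(x, class = "carrier_ledger")
}

#' Names of the ledger components
#' @return Character vector of the seven ledger fields.
#' @export
ledger_fields <- function() {
  c("fd_rd_pairs", "nadh", "nadph", "atp", "protons", "nh3", "co2")
}

#' The zero (identity) ledger
#' @return A `carrier_ledger` with every field 0.
#' @export
zero_ledger <- function() carrier_ledger()

as_ledger <- function(x) {
  if (inherits(x, "carrier_ledger")) return(x)
  stopifnot(is.numeric(x))
  full <- stats::setNames(numeric(7L), ledger_fields())
  if (is.null(names(x))) stopifnot(length(x) == 7L)
  if (is.null(names(x))) full[] <- x else {
    bad <- setdiff(names(x), ledger_fields())
    if (length(bad)) stop("unknown ledger field(s): ", paste(bad, collapse = ", "))
    full[names(x)] <- x
  }
  structure(full, class = "carrier_ledger")
}

#' @export
`+.carrier_ledger` <- function(e1, e2) {
  structure(unclass(as_ledger(e1)) + unclass(as_ledger(e2)),
            class = "carrier_ledger")
}

#' @export
`-.carrier_ledger` <- function(e1, e2) {
  if (missing(e2)) return(structure(-unclass(e1), class = "carrier_ledger"))
  structure(unclass(as_ledger(e1)) - unclass(as_ledger(e2)),
            class = "carrier_ledger")
}

#' @export
`*.carrier_ledger` <- function(e1, e2) {
  if (inherits(e1, "carrier_ledger")) {
    l <- e1; k <- e2
  } else {
    l <- e2; k <- e1
  }
  stopifnot(is.numeric(k), length(k) == 1L)
  structure(unclass(l) * k, class = "carrier_ledger")
}

#' @export
print.carrier_ledger <- function(x, ...) {
  cat("<carrier_ledger>\n")
  v <- unclass(x)
  nz <- v[v != 0]
  if (!length(nz)) cat("  (zero ledger)\n")
  else for (n in names(nz)) cat(sprintf("  %-12s %+g\n", n, nz[[n]]))
  invisible(x)
}

#' Electron pairs held by the three carriers of a ledger
#'
#' The total pair content (Fd_rd pairs + NADH + NADPH) is what Rnf and Nfn
#' conserve: both enzymes interconvert carriers without changing this sum.
#' @param ledger a `carrier_ledger`.
#' @return Numeric scalar, electron pairs.
#' @export
carrier_pairs <- function(ledger) {
  ledger <- as_ledger(ledger)
  unname(ledger[["fd_rd_pairs"]] + ledger[["nadh"]] + ledger[["nadph"]])
}

#' Electrons held by the carriers of a ledger
#' @param ledger a `carrier_ledger`.
#' @return Numeric scalar, electrons (2 per carrier pair).
#' @export
carrier_electrons <- function(ledger) 2 * carrier_pairs(ledger)
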