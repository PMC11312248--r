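#' GAFF-derived reference bond lengths per Sybyl atom type
#'
#' Equilibrium bond lengths (Angstrom) from the General Amber Force Field
#' for the bond most characteristic of each Sybyl atom type (homonuclear
#' where meaningful, else the typical bond to carbon). These are the raw
#' lengths from which the default clustering search radii are derived by a
#' 5% reduction; aromatic types are handled separately (fixed 1.38 A
#' cutoff, see [defaultCutoffs()]). Versioned constant; user-supplied JSON
#' overrides always win.
#'
#' @return named numeric vector of bond lengths in Angstrom.
#' @export
gaffBondLengths <- function() {
  c(
    "C.3"   = 1.535,  # c3-c3 sp3 C-C
    "C.2"   = 1.324,  # c2=c2 sp2 C=C
    "C.1"   = 1.181,  # c1#c1 sp C#C
    "C.ar"  = 1.387,  # aromatic CC (cutoff overridden to 1.38 fixed)
    "N.3"   = 1.402,  # n3-n3 amine N-N
    "N.2"   = 1.247,  # n2=n2 imine/azo N=N
    "N.1"   = 1.120,  # n1#n1 sp N#N
    "N.ar"  = 1.340,  # aromatic CN (cutoff overridden to 1.38 fixed)
    "N.am"  = 1.335,  # amide C-N
    "N.pl3" = 1.380,  # trigonal planar C-N (not aromatic)
    "N.4"   = 1.471,  # protonated amine C-N
    "O.3"   = 1.430,  # ether/alcohol C-O
    "O.2"   = 1.229,  # carbonyl C=O
    "O.co2" = 1.250,  # carboxylate C-O
    "S.3"   = 1.810,  # thioether C-S
    "S.2"   = 1.670,  # thiocarbonyl C=S
    "S.o"   = 1.490,  # sulfoxide S=O
    "S.o2"  = 1.440,  # sulfone S=O
    "P.3"   = 1.800,  # phosphorus C-P/P-O
    "H"     = 1.090,  # C-H
    "F"     = 1.350,  # C-F
    "Cl"    = 1.770,  # C-Cl
    "Br"    = 1.940,  # C-Br
    "I"     = 2.160   # C-I
  )
}

.AROMATIC_CUTOFF <- 1.38

.isAromaticType <- function(type) grepl("\\.ar$", type)

#' Default clustering search radii
#'
#' Builds the default [CutoffTable-class]: for every non-aromatic Sybyl
#' type in [gaffBondLengths()], the cutoff is the GAFF length reduced by
#' 5%; every aromatic type (`.ar` suffix) gets the fixed value 1.38 A.
#' Types absent from the table resolve to `globalFallback`.
#'
#' @param globalFallback cutoff (Angstrom) for types not listed in the
#'   table; the `--cutoff` CLI value.
#' @return a [CutoffTable-class].
#' @export
defaultCutoffs <- function(globalFallback = 1.0) {
  lens <- gaffBondLengths()
  cut <- lens * 0.95
  cut[.isAromaticType(names(cut))] <- .AROMATIC_CUTOFF
  new("CutoffTable", cutoffs = cut, globalFallback = globalFallback)
}

#' Look up the cutoff for one or more Sybyl types
#'
#' @param table a [CutoffTable-class].
#' @param types character vector of Sybyl types.
#' @return numeric vector of cutoffs (Angstrom); unlisted types resolve to
#'   the table's global fallback.
#' @export
cutoffFor <- function(table, types) {
  stopifnot(is(table, "CutoffTable"))
  out <- table@cutoffs[types]
  out[is.na(out)] <- table@globalFallback
  unname(out)
}

#' Render the effective cutoff table as printable lines
#'
#' One `type<TAB>cutoff` line per type, the format emitted by the
#' `--showcutoffs` CLI option.
#'
#' @param table a [CutoffTable-class].
#' @return character vector of lines.
#' @export
formatCutoffs <- function(table) {
  stopifnot(is(table, "CutoffTable"))
  cut <- table@cutoffs[order(names(table@cutoffs))]
  c(sprintf("%s\t%.4f", names(cut), cut),
    sprintf("*\t%.4f", table@globalFallback))
}
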