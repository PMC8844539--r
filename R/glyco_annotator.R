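# Monoisotopic atomic masses (CODATA/IUPAC) and permethylated residue
# increments. Residue masses are derived from elemental formulas at load
# time rather than hard-coded, so the [M+Na]+ convention is auditable from
# a single source of truth.
ATOMIC_MASS <- c(C = 12.0, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, Na = 22.9897692809)
ELECTRON_MASS <- 5.48579909e-4

RESIDUE_FORMULA <- list(
  Hex    = c(C = 9,  H = 16, O = 5),          # permethylated hexose
  HexNAc = c(C = 11, H = 19, N = 1, O = 5),   # permethylated N-acetylhexosamine
  dHex   = c(C = 8,  H = 14, O = 4),          # permethylated deoxyhexose (Fuc)
  NeuAc  = c(C = 16, H = 27, N = 1, O = 8),   # permethylated N-acetylneuraminic acid
  NeuGc  = c(C = 17, H = 29, N = 1, O = 9),   # permethylated N-glycolylneuraminic acid
  Pent   = c(C = 7,  H = 12, O = 4)           # permethylated pentose
)
END_GROUP_FORMULA <- c(C = 2, H = 6, O = 1)   # permethylated free reducing end
REDUCED_EXTRA_FORMULA <- c(C = 1, H = 4)      # alditol (reduced) end: + CH4

formula_mass <- function(formula) {
  sum(ATOMIC_MASS[names(formula)] * formula)
}

RESIDUE_MASS <- vapply(RESIDUE_FORMULA, formula_mass, numeric(1))
END_GROUP_MASS <- formula_mass(END_GROUP_FORMULA)
ADDUCT_MASS <- c(Na = unname(ATOMIC_MASS["Na"]) - ELECTRON_MASS)
RESIDUE_NAMES <- names(RESIDUE_FORMULA)

#' Glycan residue mass table
#'
#' Monoisotopic masses (Da) of permethylated residue increments, the
#' permethylated free-reducing end group, and the Na+ adduct, all computed
#' from elemental formulas and standard atomic monoisotopic masses.
#'
#' @return A list with `residue_mass` (named numeric), `reducing_end_mass`,
#'   and `adduct_mass` (named numeric, currently `Na`).
#' @export
mass_table <- function() {
  list(residue_mass = RESIDUE_MASS,
       reducing_end_mass = END_GROUP_MASS,
       adduct_mass = ADDUCT_MASS)
}

#' Construct a glycan composition
#'
#' A monosaccharide count vector over \{Hex, HexNAc, dHex, NeuAc, NeuGc,
#' Pent\}. Compositions add componentwise with `+`.
#'
#' @param Hex,HexNAc,dHex,NeuAc,NeuGc,Pent Non-negative integer counts.
#' @return Named integer vector of class `glycan_composition`.
#' @export
glycan_composition <- function(Hex = 0, HexNAc = 0, dHex = 0, NeuAc = 0,
                               NeuGc = 0, Pent = 0) {
  counts <- c(Hex = Hex, HexNAc = HexNAc, dHex = dHex, NeuAc = NeuAc,
              NeuGc = NeuGc, Pent = Pent)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("residue counts must be non-negative integers")
  structure(as.integer(counts), names = RESIDUE_NAMES,
            class = "glycan_composition")
}

#' Parse a composition string
#'
#' Grammar: residue name immediately followed by its count, concatenated in
#' any order, e.g. `"Hex3HexNAc1NeuAc1"`. Unknown residues or trailing text
#' are errors.
#'
#' @param x Composition string.
#' @return A [glycan_composition()].
#' @export
parse_composition <- function(x) {
  x <- gsub("\\s", "", x)
  # longest names first so Hex does not swallow HexNAc's prefix
  pat <- "(HexNAc|NeuAc|NeuGc|dHex|Pent|Hex)([0-9]+)"
  ml <- gregexpr(pat, x, perl = TRUE)
  m <- ml[[1]]
  if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(x))
    stop("cannot parse composition string: '", x, "'")
  tokens <- regmatches(x, ml)[[1]]
  counts <- stats::setNames(rep(0L, length(RESIDUE_NAMES)), RESIDUE_NAMES)
  for (tok in tokens) {
    res <- sub("[0-9]+$", "", tok)
    counts[res] <- counts[res] + as.integer(sub("^[A-Za-z]+", "", tok))
  }
  do.call(glycan_composition, as.list(counts))
}

#' @export
format.glycan_composition <- function(x, ...) {
  nz <- x[x > 0]
  if (!length(nz)) return("(empty)")
  paste0(names(nz), as.integer(nz), collapse = "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' @export
`+.glycan_composition` <- function(e1, e2) {
  structure(as.integer(unclass(e1) + unclass(e2)), names = RESIDUE_NAMES,
            class = "glycan_composition")
}

as_composition <- function(x) {
  if (inherits(x, "glycan_composition")) x
  else if (is.character(x)) parse_composition(x)
  else if (is.numeric(x) && !is.null(names(x)))
    do.call(glycan_composition,
            as.list(x[intersect(names(x), RESIDUE_NAMES)]))
  else stop("cannot interpret as a glycan composition")
}

#' Theoretical m/z of a permethylated sodiated glycan
#'
#' Monoisotopic m/z of the singly sodiated, permethylated, free-reducing
#' glycan: the sum of residue increments plus the permethylated reducing-end
#' group plus the Na+ adduct. `reduced = TRUE` switches to the alditol
#' (reduced-end) convention.
#'
#' @param composition A [glycan_composition()], a composition string, or a
#'   named count vector.
#' @param adduct Adduct name; only `"Na"` is defined.
#' @param reduced Use the reduced (alditol) end-group convention
#'   (default `FALSE`, free reducing end).
#' @return Monoisotopic m/z in Da.
#' @export
permethylated_mz <- function(composition, adduct = "Na", reduced = FALSE) {
  comp <- as_composition(composition)
  if (!adduct %in% names(ADDUCT_MASS))
    stop("unknown adduct: ", adduct)
  mz <- sum(unclass(comp) * RESIDUE_MASS) + END_GROUP_MASS +
    ADDUCT_MASS[[adduct]]
  if (reduced) mz <- mz + formula_mass(REDUCED_EXTRA_FORMULA)
  unname(mz)
}

#' Nominal (integer-label) m/z
#'
#' Nearest integer of the monoisotopic \[M+Na\]+ m/z, matching how MALDI
#' peaks are conventionally labelled.
#'
#' @inheritParams permethylated_mz
#' @return Integer m/z label.
#' @export
nominal_mz <- function(composition, adduct = "Na", reduced = FALSE) {
  as.integer(round(permethylated_mz(composition, adduct, reduced)))
}

#' Enumerate candidate glycan compositions under class constraints
#'
#' Generates all compositions within per-residue bounds that satisfy the
#' biosynthetic constraints of the glycan class. `N_GLYCAN`: at least the
#' Man3GlcNAc2 core (`HexNAc >= 2`, `Hex >= 3`) and at most one sialic acid
#' per antenna plus one (`NeuAc + NeuGc <= HexNAc - 1`). `GLYCOLIPID`:
#' `Hex >= 2` (the lactosylceramide core) and no fucose unless a `dHex`
#' bound is given. Output is in deterministic lexicographic order of the
#' count vectors (Hex, HexNAc, dHex, NeuAc, NeuGc, Pent).
#'
#' @param glycan_class `"N_GLYCAN"` or `"GLYCOLIPID"`.
#' @param bounds Named list/vector of per-residue maxima; unnamed residues
#'   default to 0.
#' @return List of [glycan_composition()] objects.
#' @export
enumerate_compositions <- function(glycan_class = c("N_GLYCAN", "GLYCOLIPID"),
                                   bounds) {
  glycan_class <- match.arg(glycan_class)
  b <- stats::setNames(rep(0L, length(RESIDUE_NAMES)), RESIDUE_NAMES)
  common <- intersect(names(bounds), RESIDUE_NAMES)
  b[common] <- as.integer(unlist(bounds[common]))
  if (all(b == 0)) return(list())
  grid <- expand.grid(lapply(b, function(mx) 0:mx), KEEP.OUT.ATTRS = FALSE)
  sia <- grid$NeuAc + grid$NeuGc
  keep <- if (glycan_class == "N_GLYCAN") {
    grid$HexNAc >= 2 & grid$Hex >= 3 & sia <= grid$HexNAc - 1
  } else {
    grid$Hex >= 2
  }
  grid <- grid[keep & rowSums(grid) > 0, , drop = FALSE]
  ord <- do.call(order, as.list(grid))
  grid <- grid[ord, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i)
    do.call(glycan_composition, as.list(grid[i, ])))
}

#' Annotate MALDI peaks with candidate compositions
#'
#' Matches every peak to all candidate compositions whose theoretical
#' \[M+Na\]+ m/z lies within `tolerance_da`, ordered by absolute mass error.
#' Unmatched peaks are returned flagged.
#'
#' @param peaks A [peak_list()].
#' @param candidates List of compositions (objects or strings).
#' @param tolerance_da Match tolerance in Da (default 0.5, MALDI-TOF
#'   reflectron scale).
#' @param reduced Passed to [permethylated_mz()].
#' @return A list of class `annotated_peaks`: `peaks` (data frame with
#'   `observed_mz`, `intensity`, `matched`, `best_composition`,
#'   `theoretical_mz`, `error_da`, `n_matches`) and `matches` (long data
#'   frame of all matches with `peak` index).
#' @export
annotate_peaks <- function(peaks, candidates, tolerance_da = 0.5,
                           reduced = FALSE) {
  if (length(candidates) == 0L) stop("no candidate compositions")
  if (tolerance_da <= 0) stop("tolerance must be positive")
  comps <- lapply(candidates, as_composition)
  theo <- vapply(comps, permethylated_mz, numeric(1), reduced = reduced)
  labels <- vapply(comps, format, character(1))
  match_rows <- list()
  pk <- data.frame(observed_mz = peaks$mz, intensity = peaks$intensity,
                   matched = FALSE, best_composition = NA_character_,
                   theoretical_mz = NA_real_, error_da = NA_real_,
                   n_matches = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(pk))) {
    err <- pk$observed_mz[i] - theo
    hit <- which(abs(err) <= tolerance_da)
    if (length(hit)) {
      hit <- hit[order(abs(err[hit]))]
      pk$matched[i] <- TRUE
      pk$best_composition[i] <- labels[hit[1]]
      pk$theoretical_mz[i] <- theo[hit[1]]
      pk$error_da[i] <- err[hit[1]]
      pk$n_matches[i] <- length(hit)
      match_rows[[length(match_rows) + 1L]] <-
        data.frame(peak = i, composition = labels[hit],
                   theoretical_mz = theo[hit], error_da = err[hit],
                   stringsAsFactors = FALSE)
    }
  }
  matches <- if (length(match_rows)) do.call(rbind, match_rows)
             else data.frame(peak = integer(0), composition = character(0),
                             theoretical_mz = numeric(0),
                             error_da = numeric(0))
  structure(list(peaks = pk, matches = matches,
                 tolerance_da = tolerance_da),
            class = "annotated_peaks")
}

# Monoisotopic mass of the NeuGc - NeuAc substitution (CH2O)
NEUGC_NEUAC_SHIFT <- formula_mass(c(C = 1, H = 2, O = 1))

#' NeuAc/NeuGc counterpart intensity ratios
#'
#' For pairs of compositions differing only by NeuAc <-> NeuGc substitution
#' (their mass difference is a multiple of the CH2O shift, 30.0106 Da), the
#' ratio is `I(NeuAc) / (I(NeuAc) + I(NeuGc))`, with an absent peak
#' contributing zero intensity. Intensities are summed over peaks whose best
#' annotation equals the composition.
#'
#' @param annotated An [annotate_peaks()] result.
#' @param pairs List of two-element lists/vectors `(NeuAc composition,
#'   NeuGc composition)` as objects or strings.
#' @return A `data.frame` with columns `neuac`, `neugc`,
#'   `intensity_neuac`, `intensity_neugc`, `ratio`, `flag` (`"ok"`,
#'   `"neugc_absent"`, `"neuac_absent"`, or `"both_absent"`; ratio `NA`
#'   when both absent).
#' @export
neuac_neugc_ratio <- function(annotated, pairs) {
  pk <- annotated$peaks
  total_intensity <- function(label)
    sum(pk$intensity[pk$matched & pk$best_composition == label])
  out <- do.call(rbind, lapply(pairs, function(pr) {
    ac <- as_composition(pr[[1]]); gc <- as_composition(pr[[2]])
    dm <- permethylated_mz(gc) - permethylated_mz(ac)
    k <- dm / NEUGC_NEUAC_SHIFT
    if (k < 1 - 1e-6 || abs(k - round(k)) > 1e-6)
      stop("pair ", format(ac), " / ", format(gc),
           " does not differ by a NeuAc->NeuGc substitution")
    ia <- total_intensity(format(ac)); ig <- total_intensity(format(gc))
    flag <- if (ia == 0 && ig == 0) "both_absent"
            else if (ig == 0) "neugc_absent"
            else if (ia == 0) "neuac_absent" else "ok"
    data.frame(neuac = format(ac), neugc = format(gc),
               intensity_neuac = ia, intensity_neugc = ig,
               ratio = if (ia + ig > 0) ia / (ia + ig) else NA_real_,
               flag = flag, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
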