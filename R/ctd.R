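#' Canonical three-group physicochemical partitions
#'
#' The eight amino-acid groupings behind the 188D descriptor's
#' composition/transition/distribution (CTD) block. Each property partitions
#' the 20 amino acids into three disjoint, jointly exhaustive, ordered
#' groups (the canonical Dubchak-style tables used by SVM-Prot-family
#' encoders). The property order and the within-property group order are
#' frozen: they define feature-column identity. Alternative tables can be
#' supplied to [encode188()] via [readGroupings()].
#'
#' @return Named list of 8 groupings, each a list of three named character
#'   vectors (`grp1`, `grp2`, `grp3`).
#' @export
#' @examples
#' ctdGroupings()$charge
ctdGroupings <- function() {
  g <- function(a, b, c3) list(grp1 = splitResidues(a),
                               grp2 = splitResidues(b),
                               grp3 = splitResidues(c3))
  list(
    hydrophobicity        = g("RKEDQN",   "GASTPHY",          "CLVIMFW"),
    normalized_vdw_volume = g("GASTPDC",  "NVEQIL",           "MHKFRYW"),
    polarity              = g("LIFWCMVY", "PATGS",            "HQRKNED"),
    polarizability        = g("GASDT",    "CPNVEQIL",         "KMHFRYW"),
    charge                = g("KR",       "ANCQGHILMFPSTWYV", "DE"),
    secondary_structure   = g("EALMQKRH", "VIYCWFT",          "GNPSD"),
    solvent_accessibility = g("ALFCGIVW", "RKQEND",           "MSPTHY"),
    surface_tension       = g("GQDNAHR",  "KTSEC",            "ILMFPWYV")
  )
}

# Short column-name prefixes, same order as ctdGroupings().
.CTD_PREFIX <- c(hydrophobicity = "hydro", normalized_vdw_volume = "vdw",
                 polarity = "polarity", polarizability = "polariz",
                 charge = "charge", secondary_structure = "ss",
                 solvent_accessibility = "solva", surface_tension = "tension")

checkGrouping <- function(grouping, property = "grouping") {
  all20 <- sort(unlist(grouping, use.names = FALSE))
  if (length(grouping) != 3L || !identical(all20, aminoAcids()))
    stop(sprintf("%s: the three groups must partition the 20-letter alphabet",
                 property))
  invisible(grouping)
}

#' Amino-acid composition frequencies
#'
#' The 20 composition features: entry i is the count of amino acid i divided
#' by the sequence length, in the alphabetical residue order of
#' [aminoAcids()]. Entries sum to 1 for any non-empty sequence.
#'
#' @param seq A single validated sequence string.
#' @return Named numeric vector of 20 frequencies.
#' @export
#' @examples
#' composition20("ACDG")[c("A", "C", "D", "G")]
composition20 <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  res <- splitResidues(seq)
  counts <- table(factor(res, levels = aminoAcids()))
  stats::setNames(as.vector(counts) / length(res),
                  paste0("comp_", aminoAcids()))
}

#' Composition/transition/distribution features for one property
#'
#' The 21 CTD values of a sequence under a three-group partition:
#' \describe{
#'   \item{composition (3)}{fraction of residues in group 1, 2, 3.}
#'   \item{transition (3)}{frequency of adjacent residue pairs crossing
#'     between distinct groups (1<->2, 1<->3, 2<->3, both directions
#'     counted), divided by the number of adjacent pairs `L - 1`. A
#'     length-1 sequence has no pairs; its transitions are 0.}
#'   \item{distribution (15)}{for each group, the 1-based sequence positions
#'     of the first occurrence, the `ceiling(n * q)`-th occurrence for
#'     q = 25%, 50%, 75% (n = number of occurrences of that group), and the
#'     last occurrence, each divided by `L`. A group with no occurrences
#'     contributes five zeros.}
#' }
#'
#' @param seq A single validated sequence string.
#' @param grouping One element of [ctdGroupings()] (a list of three
#'   character vectors partitioning the alphabet).
#' @return Named numeric vector of 21 values in `[0, 1]`.
#' @export
#' @examples
#' ctd21("ARNDC", ctdGroupings()$charge)
ctd21 <- function(seq, grouping) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("empty sequence")
  checkGrouping(grouping)
  res <- splitResidues(seq)
  L <- length(res)
  groupOf <- integer(20)
  names(groupOf) <- aminoAcids()
  for (gi in 1:3) groupOf[grouping[[gi]]] <- gi
  gidx <- groupOf[res]

  comp <- tabulate(gidx, nbins = 3L) / L

  trans <- numeric(3)
  if (L > 1L) {
    a <- gidx[-L]; b <- gidx[-1L]
    trans[1] <- sum((a == 1L & b == 2L) | (a == 2L & b == 1L))
    trans[2] <- sum((a == 1L & b == 3L) | (a == 3L & b == 1L))
    trans[3] <- sum((a == 2L & b == 3L) | (a == 3L & b == 2L))
    trans <- trans / (L - 1L)
  }

  distr <- numeric(15)
  for (gi in 1:3) {
    pos <- which(gidx == gi)
    n <- length(pos)
    if (n > 0L) {
      ks <- c(1L, pmax(1L, ceiling(n * c(0.25, 0.5, 0.75))), n)
      distr[(gi - 1L) * 5L + 1:5] <- pos[ks] / L
    }
  }

  nm <- c(paste0("grp", 1:3, "_comp"), c("T12", "T13", "T23"),
          paste0(rep(paste0("grp", 1:3), each = 5L), "_",
                 rep(c("D0", "D25", "D50", "D75", "D100"), 3L)))
  stats::setNames(c(comp, trans, distr), nm)
}

#' The 188-dimensional sequence descriptor
#'
#' Concatenates the 20 composition frequencies with eight 21-value CTD
#' blocks, one per physicochemical property, in the frozen order of
#' [ctdGroupings()]: 20 + 8 x 21 = 188 features, all in `[0, 1]`.
#'
#' @param seq A single validated sequence string.
#' @param groupings List of 8 named groupings (default [ctdGroupings()]).
#' @return Named numeric vector of length 188.
#' @export
#' @examples
#' length(encode188("GLFDIIKKIAESF"))
encode188 <- function(seq, groupings = ctdGroupings()) {
  if (length(groupings) != 8L)
    stop("exactly 8 grouping tables are required")
  blocks <- lapply(names(groupings), function(p) {
    v <- ctd21(seq, groupings[[p]])
    pre <- if (p %in% names(.CTD_PREFIX)) .CTD_PREFIX[[p]] else p
    stats::setNames(v, paste0(pre, "_", names(v)))
  })
  c(composition20(seq), unlist(blocks))
}

#' Read / write grouping tables as plain-text config
#'
#' One property per line: `name: GROUP1 | GROUP2 | GROUP3`, groups written
#' as runs of one-letter residue codes. Lines starting with `#` are
#' comments.
#'
#' @param path File path.
#' @return `readGroupings` returns a named list of groupings (validated as
#'   partitions); `writeGroupings` returns `path` invisibly.
#' @export
readGroupings <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^#", lines)])
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed grouping line: ", ln)
    name <- trimws(parts[1])
    grps <- trimws(strsplit(parts[2], "|", fixed = TRUE)[[1]])
    if (length(grps) != 3L) stop("expected 3 groups in line: ", name)
    out[[name]] <- checkGrouping(
      list(grp1 = splitResidues(grps[1]), grp2 = splitResidues(grps[2]),
           grp3 = splitResidues(grps[3])), name)
  }
  out
}

#' @rdname readGroupings
#' @param groupings Named list of groupings.
#' @export
writeGroupings <- function(groupings, path) {
  lines <- vapply(names(groupings), function(p) {
    sprintf("%s: %s | %s | %s", p,
            paste(groupings[[p]][[1]], collapse = ""),
            paste(groupings[[p]][[2]], collapse = ""),
            paste(groupings[[p]][[3]], collapse = ""))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
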