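# Structure-derived quantities: residue-residue minimum heavy-atom
# distances, contact maps, solvent accessibility (parsed from Naccess-style
# .rsa files or computed internally by a Shrake-Rupley sphere-point
# approximation), burial classes, and volume-weighted pair accessibility.

# Mean amino-acid residue volumes in cubic Angstrom (Zamyatnin 1972).
RESIDUE_VOLUME <- c(
  ALA = 88.6, ARG = 173.4, ASN = 114.1, ASP = 111.1, CYS = 108.5,
  GLN = 143.8, GLU = 138.4, GLY = 60.1, HIS = 153.2, ILE = 166.7,
  LEU = 166.7, LYS = 168.6, MET = 162.9, PHE = 189.9, PRO = 112.7,
  SER = 89.0, THR = 116.1, TRP = 227.8, TYR = 193.6, VAL = 140.0)

# Theoretical maximum accessible surface areas in square Angstrom
# (Tien et al. 2013), used to normalise absolute SASA to a percentage.
MAX_ASA <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0)

VDW_RADIUS <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
VDW_DEFAULT <- 1.70

residue_key <- function(chain, resno, ins = "") {
  ins <- ifelse(is.na(ins) | ins == " ", "", ins)
  paste0(chain, ":", resno, ins)
}

#' Build a structure context from atom records
#'
#' The container tying together residue coordinates, the alignment-column
#' to residue mapping, and per-residue relative accessibility.
#'
#' @param atoms `data.frame` with columns `chain`, `resno`, `ins`, `resid`
#'   (3-letter type), `x`, `y`, `z`, `element`; heavy atoms only.
#' @param map Optional `data.frame` with columns `column` (1-based
#'   alignment column), `chain`, `resno` linking columns to residues.
#' @param accessibility Optional named numeric vector (percent relative
#'   accessibility) keyed by `chain:resno`.
#' @param volumes Named per-residue-type volume table (defaults to shipped
#'   mean volumes).
#' @return Object of class `"structure_context"`.
#' @export
structure_context <- function(atoms, map = NULL, accessibility = NULL,
                              volumes = RESIDUE_VOLUME) {
  need <- c("chain", "resno", "resid", "x", "y", "z", "element")
  if (!all(need %in% names(atoms)))
    stop_invalid("atoms must have columns: %s", paste(need, collapse = ", "))
  if (is.null(atoms$ins)) atoms$ins <- ""
  atoms$key <- residue_key(atoms$chain, atoms$resno, atoms$ins)
  residues <- atoms[!duplicated(atoms$key),
                    c("key", "chain", "resno", "ins", "resid")]
  rownames(residues) <- residues$key
  if (!is.null(map)) {
    map$key <- residue_key(map$chain, map$resno)
    bad <- setdiff(map$key, residues$key)
    if (length(bad))
      stop_invalid("mapping refers to residues absent from structure: %s",
                   paste(bad, collapse = ", "))
  }
  structure(list(atoms = atoms, residues = residues, map = map,
                 accessibility = accessibility, volumes = volumes),
            class = "structure_context")
}

#' @export
print.structure_context <- function(x, ...) {
  cat(sprintf(
    "Structure context: %d residues, %d heavy atoms%s%s\n",
    nrow(x$residues), nrow(x$atoms),
    if (!is.null(x$map)) sprintf(", %d mapped columns", nrow(x$map)) else "",
    if (!is.null(x$accessibility)) ", accessibility present" else ""))
  invisible(x)
}

#' Read a PDB file into a structure context
#'
#' Uses [bio3d::read.pdb()]; keeps ATOM records of the first model,
#' preferring altloc 'A' (or blank), and drops hydrogens.
#'
#' @param path PDB file path.
#' @param chain Optional chain filter.
#' @param map,accessibility Passed to [structure_context()].
#' @return A `"structure_context"`.
#' @export
read_pdb_context <- function(path, chain = NULL, map = NULL,
                             accessibility = NULL) {
  pdb <- bio3d::read.pdb(path, multi = FALSE)
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  a <- a[is.na(a$alt) | a$alt %in% c("", "A"), , drop = FALSE]
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(gsub("[0-9 ]", "", a$elety), 1, 1)
  keep <- toupper(trimws(elem)) != "H"
  a <- a[keep, , drop = FALSE]
  atoms <- data.frame(chain = a$chain, resno = a$resno,
                      ins = ifelse(is.na(a$insert), "", a$insert),
                      resid = a$resid, x = a$x, y = a$y, z = a$z,
                      element = toupper(trimws(elem[keep])),
                      stringsAsFactors = FALSE)
  if (!is.null(chain)) atoms <- atoms[atoms$chain %in% chain, , drop = FALSE]
  if (nrow(atoms) == 0L) stop_invalid("no heavy ATOM records read from %s", path)
  structure_context(atoms, map = map, accessibility = accessibility)
}

#' Minimum heavy-atom distance between two residues
#'
#' @param context A `"structure_context"`.
#' @param keyA,keyB Residue keys (`"chain:resno"`).
#' @return Shortest Euclidean distance in Angstrom over all heavy-atom
#'   pairs; symmetric in its arguments.
#' @export
min_heavy_atom_distance <- function(context, keyA, keyB) {
  A <- context$atoms[context$atoms$key == keyA, c("x", "y", "z"), drop = FALSE]
  B <- context$atoms[context$atoms$key == keyB, c("x", "y", "z"), drop = FALSE]
  if (nrow(A) == 0L) stop_invalid("residue %s not in structure", keyA)
  if (nrow(B) == 0L) stop_invalid("residue %s not in structure", keyB)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") -
    2 * as.matrix(A) %*% t(as.matrix(B))
  sqrt(max(min(d2), 0))
}

# all-vs-all minimum heavy-atom distance matrix over residues
residue_distance_matrix <- function(context) {
  keys <- context$residues$key
  xyz <- as.matrix(context$atoms[, c("x", "y", "z")])
  g2 <- rowSums(xyz^2)
  d2_atoms <- outer(g2, g2, "+") - 2 * xyz %*% t(xyz)
  d2_atoms[d2_atoms < 0] <- 0
  f <- factor(context$atoms$key, levels = keys)
  n <- length(keys)
  D <- matrix(Inf, n, n, dimnames = list(keys, keys))
  idx <- split(seq_len(nrow(xyz)), f)
  for (i in seq_len(n)) for (j in i:n) {
    m <- sqrt(min(d2_atoms[idx[[i]], idx[[j]]]))
    D[i, j] <- D[j, i] <- m
  }
  D
}

#' Contact labels for mapped column pairs
#'
#' A pair of alignment columns is a contact iff the minimum heavy-atom
#' distance of the mapped residues is below `threshold` and the column
#' separation `|i - j|` is at least `min_separation`.
#'
#' @param context A `"structure_context"` with a column mapping.
#' @param threshold Contact distance threshold in Angstrom (> 0).
#' @param min_separation Minimum `|i - j|`; pairs closer in sequence get
#'   label `NA` (excluded), matching benchmark conventions when set > 0.
#' @return `data.frame` with columns `i`, `j`, `distance`, `contact`.
#' @export
contact_map <- function(context, threshold = 10, min_separation = 0) {
  if (threshold <= 0) stop_invalid("'threshold' must be positive")
  if (is.null(context$map)) stop_invalid("context has no column mapping")
  D <- residue_distance_matrix(context)
  m <- context$map[order(context$map$column), , drop = FALSE]
  n <- nrow(m)
  pr <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  i <- m$column[pr[, 1]]; j <- m$column[pr[, 2]]
  d <- D[cbind(m$key[pr[, 1]], m$key[pr[, 2]])]
  contact <- d < threshold
  contact[abs(i - j) < min_separation] <- NA
  out <- data.frame(i = pmin(i, j), j = pmax(i, j), distance = d,
                    contact = contact)
  out[order(out$i, out$j), , drop = FALSE]
}

#' Read a Naccess-style .rsa file
#'
#' Parses `RES` records and returns the relative all-atom accessibility
#' column (percent of the reference maximum). Naccess writes fixed-width
#' records; fields are recovered positionally, tolerating a blank chain
#' identifier.
#'
#' @param path Path to the .rsa file.
#' @return Named numeric vector keyed by `chain:resno` (chain empty when
#'   absent); attribute `"resid"` holds the 3-letter residue types.
#' @export
read_rsa <- function(path) {
  if (!file.exists(path)) stop_invalid("rsa file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  res_lines <- which(startsWith(lines, "RES"))
  if (length(res_lines) == 0L) stop_invalid("no RES records in %s", path)
  keys <- character(length(res_lines))
  vals <- numeric(length(res_lines))
  resid <- character(length(res_lines))
  for (k in seq_along(res_lines)) {
    ln <- res_lines[k]
    l <- lines[ln]
    # fixed-width: RES(1-3) resid(5-7) chain(9) resno(10-13)ins(14)
    resid[k] <- trimws(substr(l, 5, 7))
    chain <- trimws(substr(l, 9, 9))
    resno <- suppressWarnings(as.integer(trimws(substr(l, 10, 13))))
    ins <- trimws(substr(l, 14, 14))
    rest <- suppressWarnings(as.numeric(strsplit(trimws(substr(l, 15, nchar(l))),
                                                 "\\s+")[[1]]))
    if (is.na(resno) || length(rest) < 2 || any(is.na(rest[1:2])))
      stop_invalid("malformed RES record at line %d: '%s'", ln, l)
    keys[k] <- residue_key(chain, resno, ins)
    vals[k] <- rest[2]                      # relative all-atom accessibility
  }
  if (anyDuplicated(keys))
    stop_invalid("duplicate residue key(s) in %s: %s", path,
                 paste(unique(keys[duplicated(keys)]), collapse = ", "))
  names(vals) <- keys
  attr(vals, "resid") <- stats::setNames(resid, keys)
  vals
}

# evenly distributed points on the unit sphere (golden spiral); fixed count
# makes the SASA approximation deterministic
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(x = cos(theta) * sin(phi), y = sin(theta) * sin(phi), z = cos(phi))
}

#' Shrake-Rupley relative solvent accessibility
#'
#' Approximates each atom's accessible surface by testing a fixed set of
#' sphere points at radius (vdW + probe) against occlusion by neighbouring
#' atoms, sums per residue, and normalises by a per-residue-type reference
#' maximum to a percentage. An internal approximation for use when no
#' Naccess-style .rsa file is supplied.
#'
#' @param context A `"structure_context"`.
#' @param probe Probe radius in Angstrom (water, 1.4).
#' @param n_points Sphere points per atom; more points, finer surface.
#' @return Named numeric vector of percent relative accessibility keyed by
#'   residue key; residue types missing from the reference table are
#'   normalised by the table's median.
#' @export
compute_sasa <- function(context, probe = 1.4, n_points = 120L) {
  atoms <- context$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- VDW_RADIUS[atoms$element]
  r[is.na(r)] <- VDW_DEFAULT
  r <- r + probe
  pts <- sphere_points(n_points)
  n <- nrow(xyz)
  # neighbour lists by cutoff on centre distance
  maxr <- max(r)
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  area <- numeric(n)
  for (a in seq_len(n)) {
    nb <- which(d2[a, ] < (r[a] + maxr)^2 & seq_len(n) != a)
    surf <- xyz[rep(a, n_points), , drop = FALSE] + pts * r[a]
    if (length(nb)) {
      occluded <- rep(FALSE, n_points)
      for (b in nb) {
        db <- (surf[, 1] - xyz[b, 1])^2 + (surf[, 2] - xyz[b, 2])^2 +
          (surf[, 3] - xyz[b, 3])^2
        occluded <- occluded | db < r[b]^2
        if (all(occluded)) break
      }
      frac <- mean(!occluded)
    } else frac <- 1
    area[a] <- frac * 4 * pi * r[a]^2
  }
  per_res <- tapply(area, factor(atoms$key, levels = context$residues$key), sum)
  ref <- MAX_ASA[context$residues$resid]
  ref[is.na(ref)] <- stats::median(MAX_ASA)
  out <- 100 * as.numeric(per_res) / ref
  names(out) <- context$residues$key
  out
}

#' Volume-weighted mean accessibility of a residue pair
#'
#' `(vol_i * acc_i + vol_j * acc_j) / (vol_i + vol_j)`, where volumes come
#' from the context's residue-type volume table.
#'
#' @param context A `"structure_context"` with accessibility set.
#' @param keyA,keyB Residue keys.
#' @return Percentage accessibility.
#' @export
weighted_mean_accessibility <- function(context, keyA, keyB) {
  acc <- context$accessibility
  if (is.null(acc)) stop_invalid("context has no accessibility data")
  for (k in c(keyA, keyB)) if (!k %in% names(acc))
    stop_invalid("no accessibility for residue %s", k)
  typ <- context$residues[c(keyA, keyB), "resid"]
  vol <- context$volumes[typ]
  if (any(is.na(vol)))
    stop_invalid("no volume entry for residue type(s): %s",
                 paste(typ[is.na(vol)], collapse = ", "))
  sum(vol * acc[c(keyA, keyB)]) / sum(vol)
}

#' Burial class of a residue
#'
#' `completely_buried` at exactly 0% relative accessibility (within 1e-9),
#' `core` below the core threshold, `exposed` otherwise.
#'
#' @param accessibility Percent relative accessibility (scalar or vector).
#' @param core_threshold Core cutoff in percent (default 10).
#' @return Character vector of classes.
#' @export
burial_class <- function(accessibility, core_threshold = 10) {
  ifelse(abs(accessibility) < 1e-9, "completely_buried",
         ifelse(accessibility < core_threshold, "core", "exposed"))
}

#' Completely-buried pair census
#'
#' Counts residue pairs in which both residues are completely buried
#' (0% relative accessibility) and the fraction of those pairs whose
#' minimum heavy-atom distance is below the threshold.
#'
#' @param context A `"structure_context"` with accessibility set.
#' @param threshold Distance threshold in Angstrom.
#' @return List with `n_buried_residues`, `n_pairs`, and
#'   `fraction_within_threshold` (percent).
#' @export
buried_pair_summary <- function(context, threshold = 10) {
  acc <- context$accessibility
  if (is.null(acc)) stop_invalid("context has no accessibility data")
  keys <- names(acc)[burial_class(acc) == "completely_buried"]
  keys <- intersect(keys, context$residues$key)
  n <- length(keys)
  if (n < 2L)
    return(list(n_buried_residues = n, n_pairs = 0L,
                fraction_within_threshold = NA_real_))
  D <- residue_distance_matrix(context)
  d <- D[keys, keys][upper.tri(matrix(0, n, n))]
  list(n_buried_residues = n, n_pairs = length(d),
       fraction_within_threshold = 100 * mean(d < threshold))
}
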