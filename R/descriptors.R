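#' Physicochemical peptide descriptors
#'
#' Computes the descriptor vector that places peptides in the coordinate-free
#' chemical space from which the CSN is built: residue count, net charge at
#' pH 7 (Henderson-Hasselbalch, Lehninger pKa set), isoelectric point
#' (bisection of the charge curve), average molecular weight (Da), Boman
#' index (kcal/mol, mean residue solubility value), Eisenberg hydrophobic
#' moment at the 100-degree alpha-helical angle, Hopp-Woods average
#' hydrophilicity, hydrophobic periodicity (normalized Fourier amplitude of
#' the mean-centered Eisenberg profile at 100 degrees), Ikai aliphatic index
#' and Guruprasad instability index.
#'
#' @param records a `peptide_set` (sequences must be canonical; records
#'   containing `X` are rejected).
#' @param descriptors character vector selecting a subset of the default
#'   descriptor set (by column name).
#' @return Numeric matrix, one row per peptide (rownames = ids), with
#'   attribute `normalized = FALSE`.
#' @examples
#' ps <- peptide_set(c("a", "b"), c("CNGRC", "KLAKLAKKLAKLAK"))
#' peptide_descriptors(ps)
#' @export
peptide_descriptors <- function(records, descriptors = NULL) {
  stopifnot(inherits(records, "peptide_set"))
  if (any(grepl("X", records$sequence, fixed = TRUE)))
    stop("descriptor computation requires canonical sequences (no X): ",
         paste(records$id[grepl("X", records$sequence, fixed = TRUE)],
               collapse = ", "))
  rows <- t(vapply(records$sequence, .descriptor_vector, numeric(10)))
  rownames(rows) <- records$id
  if (!is.null(descriptors)) {
    missing <- setdiff(descriptors, colnames(rows))
    if (length(missing)) stop("unknown descriptor(s): ",
                              paste(missing, collapse = ", "))
    rows <- rows[, descriptors, drop = FALSE]
  }
  attr(rows, "normalized") <- FALSE
  rows
}

.descriptor_vector <- function(seq) {
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  c(length = n,
    net_charge = .net_charge(res, 7.0),
    isoelectric_point = .isoelectric_point(res),
    molecular_weight = sum(.MASS_AVG[res]) + .WATER_MASS,
    boman_index = mean(.BOMAN[res]),
    hydrophobic_moment = .hydrophobic_moment(res),
    avg_hydrophilicity = mean(.HOPP_WOODS[res]),
    hydrophobic_periodicity = .hydrophobic_periodicity(res),
    aliphatic_index = .aliphatic_index(res),
    instability_index = .instability_index(res))
}

# Henderson-Hasselbalch net charge at a given pH, termini included
.net_charge <- function(res, ph) {
  pos_pka <- c(nterm = .PKA$nterm, .PKA$positive[names(.PKA$positive)])
  pos_n <- c(1, vapply(names(.PKA$positive), function(a) sum(res == a), numeric(1)))
  neg_pka <- c(cterm = .PKA$cterm, .PKA$negative[names(.PKA$negative)])
  neg_n <- c(1, vapply(names(.PKA$negative), function(a) sum(res == a), numeric(1)))
  sum(pos_n / (1 + 10^(ph - pos_pka))) - sum(neg_n / (1 + 10^(neg_pka - ph)))
}

# pH at which the net charge crosses zero (monotone decreasing in pH)
.isoelectric_point <- function(res, tol = 1e-4) {
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    q <- .net_charge(res, mid)
    if (abs(q) < tol) return(mid)
    if (q > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Eisenberg uH = |sum h_i e^{i n delta}| / N at delta = 100 degrees
.hydrophobic_moment <- function(res, delta_deg = 100) {
  h <- .EISENBERG[res]
  ang <- (seq_along(h) - 1) * delta_deg * pi / 180
  sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / length(h)
}

# Normalized amplitude of the mean-centered hydrophobicity profile at the
# helical frequency: 0 for flat profiles, 1 when all signal sits at 100 deg
.hydrophobic_periodicity <- function(res, delta_deg = 100) {
  h <- .EISENBERG[res]
  hc <- h - mean(h)
  denom <- sum(abs(hc))
  if (denom == 0) return(0)
  ang <- (seq_along(h) - 1) * delta_deg * pi / 180
  sqrt(sum(hc * sin(ang))^2 + sum(hc * cos(ang))^2) / denom
}

# Ikai (1980): 100 * (xA + 2.9 xV + 3.9 (xI + xL)), mole fractions
.aliphatic_index <- function(res) {
  n <- length(res)
  100 * (sum(res == "A") + 2.9 * sum(res == "V") +
           3.9 * (sum(res == "I") + sum(res == "L"))) / n
}

# Guruprasad (1990): (10 / L) * sum of DIWV over consecutive dipeptides
.instability_index <- function(res) {
  n <- length(res)
  if (n < 2) return(0)
  idx <- cbind(res[-n], res[-1])
  10 / n * sum(.DIWV[idx])
}

#' Min-max normalize a descriptor matrix
#'
#' Maps every column to \[0, 1\] by `(x - min) / (max - min)`. Constant
#' columns carry no distance information and map to all zeros. Already
#' normalized matrices pass through unchanged.
#'
#' @param m a descriptor matrix from [peptide_descriptors()] (>= 2 rows).
#' @return The normalized matrix with attribute `normalized = TRUE`.
#' @export
minmax_normalize <- function(m) {
  if (nrow(m) < 2) stop("need at least 2 peptides to normalize")
  if (isTRUE(attr(m, "normalized"))) return(m)
  out <- apply(m, 2, function(x) {
    rng <- range(x)
    if (rng[1] == rng[2]) rep(0, length(x)) else (x - rng[1]) / (rng[2] - rng[1])
  })
  rownames(out) <- rownames(m)
  attr(out, "normalized") <- TRUE
  out
}
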