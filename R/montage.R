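#' Default 25-electrode 10-20 montage
#'
#' Builds the 25-channel 10-20 scalp layout used throughout the package:
#' electrode names, 2-D unit-disc positions (x towards the right ear, y
#' towards the nasion), a symmetric neighbour map of up to eight neighbours
#' per electrode, and a region tag per electrode (\code{frontal},
#' \code{parietal} or \code{other}).  The frontal set carries the theta-band
#' features and the parietal set the alpha-band features of the Dual
#' Frequency Head Maps.
#'
#' The region assignment is a declared convention of this package: frontal =
#' Fp1, Fp2, F7, F3, Fz, F4, F8, FC3, FCz, FC4; parietal = CP3, CPz, CP4, P7,
#' P3, Pz, P4, P8, PO7, PO8.  Neighbours are the mutual 8-nearest electrodes
#' by Euclidean distance on the 2-D projection; a candidate farther than 1.5
#' times the median nearest-neighbour distance is dropped so that border
#' electrodes do not pair across the scalp edge.  Mutuality makes the
#' neighbour relation symmetric by construction.
#'
#' @return An object of class \code{dfhm_montage}: a list with
#'   \code{electrode_names}, \code{positions} (matrix with columns x, y),
#'   \code{neighbor_map} (named list of character vectors), and
#'   \code{region} (named character vector).
#' @export
default_montage <- function() {
  pos <- matrix(c(
    -0.31,  0.95,   # Fp1
     0.31,  0.95,   # Fp2
    -0.81,  0.59,   # F7
    -0.40,  0.62,   # F3
     0.00,  0.64,   # Fz
     0.40,  0.62,   # F4
     0.81,  0.59,   # F8
    -0.42,  0.32,   # FC3
     0.00,  0.32,   # FCz
     0.42,  0.32,   # FC4
    -1.00,  0.00,   # T7
    -0.50,  0.00,   # C3
     0.00,  0.00,   # Cz
     0.50,  0.00,   # C4
     1.00,  0.00,   # T8
    -0.42, -0.32,   # CP3
     0.00, -0.32,   # CPz
     0.42, -0.32,   # CP4
    -0.81, -0.59,   # P7
    -0.40, -0.62,   # P3
     0.00, -0.64,   # Pz
     0.40, -0.62,   # P4
     0.81, -0.59,   # P8
    -0.50, -0.81,   # PO7
     0.50, -0.81    # PO8
  ), ncol = 2, byrow = TRUE)
  names_ <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC3", "FCz", "FC4",
              "T7", "C3", "Cz", "C4", "T8", "CP3", "CPz", "CP4",
              "P7", "P3", "Pz", "P4", "P8", "PO7", "PO8")
  rownames(pos) <- names_
  colnames(pos) <- c("x", "y")
  frontal <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "FC3", "FCz", "FC4")
  parietal <- c("CP3", "CPz", "CP4", "P7", "P3", "Pz", "P4", "P8", "PO7", "PO8")
  region <- stats::setNames(rep("other", length(names_)), names_)
  region[frontal] <- "frontal"
  region[parietal] <- "parietal"
  new_montage(names_, pos, region)
}

new_montage <- function(electrode_names, positions, region, k = 8,
                        reach = 1.5) {
  d <- as.matrix(stats::dist(positions))
  diag(d) <- Inf
  # cutoff: 1.5x the median of all k-nearest-neighbour distances, so border
  # electrodes drop far-away candidates instead of pairing across the edge
  knn_d <- apply(d, 1, function(r) sort(r)[seq_len(min(k, length(r) - 1))])
  cutoff <- reach * stats::median(knn_d)
  cand <- lapply(electrode_names, function(e) {
    ord <- order(d[e, ])
    nb <- electrode_names[ord][seq_len(min(k, length(ord)))]
    nb[d[e, nb] <= cutoff]
  })
  names(cand) <- electrode_names
  # mutual k-NN: keep B in N(A) only if A is also in N(B) -> symmetric
  neighbor_map <- lapply(electrode_names, function(e) {
    nb <- cand[[e]]
    nb[vapply(nb, function(b) e %in% cand[[b]], logical(1))]
  })
  names(neighbor_map) <- electrode_names
  structure(list(electrode_names = electrode_names,
                 positions = positions,
                 neighbor_map = neighbor_map,
                 region = region),
            class = "dfhm_montage")
}

#' Frontal / parietal electrode sets of a montage
#'
#' @param montage a \code{dfhm_montage}
#' @return character vector of electrode names, in montage order.
#' @export
frontal_electrodes <- function(montage) {
  montage$electrode_names[montage$region[montage$electrode_names] == "frontal"]
}

#' @rdname frontal_electrodes
#' @export
parietal_electrodes <- function(montage) {
  montage$electrode_names[montage$region[montage$electrode_names] == "parietal"]
}

#' @export
print.dfhm_montage <- function(x, ...) {
  cat("<dfhm_montage> ", length(x$electrode_names), " electrodes (",
      sum(x$region == "frontal"), " frontal, ",
      sum(x$region == "parietal"), " parietal)\n", sep = "")
  invisible(x)
}

#' Read / write a montage as JSON
#'
#' The JSON carries electrode names, x/y unit-disc coordinates and region
#' tags; the neighbour map is rebuilt deterministically from the coordinates.
#'
#' @param montage a \code{dfhm_montage}
#' @param path file path
#' @return \code{read_montage} returns a \code{dfhm_montage};
#'   \code{write_montage} returns \code{path} invisibly.
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(name = montage$electrode_names,
                   x = montage$positions[, "x"],
                   y = montage$positions[, "y"],
                   region = unname(montage$region[montage$electrode_names]))
  jsonlite::write_json(df, path, digits = NA)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  pos <- as.matrix(df[, c("x", "y")])
  rownames(pos) <- df$name
  new_montage(df$name, pos, stats::setNames(df$region, df$name))
}
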