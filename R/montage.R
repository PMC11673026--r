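#' Channel labels of the 128-channel geodesic montage
#'
#' Labels follow the E1...E128 convention used by high-density geodesic
#' sensor nets.
#'
#' @return Character vector of 128 labels.
#' @export
geodesic_labels <- function() paste0("E", 1:128)

#' Idealized electrode positions for neighbor computations
#'
#' Returns 3-D unit-hemisphere coordinates for the requested channel labels.
#' The layout is a synthetic, quasi-uniform hemispheric arrangement (Fibonacci
#' spiral), not the vendor's digitized geodesic coordinates; it is used only
#' for distance-weighted neighbor interpolation of rejected channels, where a
#' smooth, roughly even spacing is all that matters.
#'
#' @param labels Channel labels, a subset of [geodesic_labels()].
#' @return Numeric matrix with one row per label and columns x, y, z.
#' @export
montage_positions <- function(labels = geodesic_labels()) {
  all_labels <- geodesic_labels()
  bad <- setdiff(labels, all_labels)
  if (length(bad) > 0) {
    stop("unknown channel labels: ", paste(bad, collapse = ", "))
  }
  n <- length(all_labels)
  i <- seq_len(n) - 1
  golden <- pi * (3 - sqrt(5))
  z <- (i + 0.5) / n          # height on the upper hemisphere, (0, 1)
  r <- sqrt(pmax(0, 1 - z^2))
  theta <- golden * i
  pos <- cbind(x = r * cos(theta), y = r * sin(theta), z = z)
  rownames(pos) <- all_labels
  pos[labels, , drop = FALSE]
}

#' Frontal electrode clusters used for alpha asymmetry
#'
#' The left and right frontal clusters over which alpha power is averaged
#' before the asymmetry log-ratio is taken.
#'
#' @param left,right Character vectors of channel labels. Defaults are the
#'   standard frontal clusters for the 128-channel geodesic net.
#' @return An object of class `cluster_spec`: a list with elements `left`
#'   and `right`.
#' @export
cluster_spec <- function(left = c("E23", "E24", "E26", "E27", "E33"),
                         right = c("E2", "E3", "E122", "E123", "E124")) {
  left <- as.character(left)
  right <- as.character(right)
  if (length(left) == 0 || length(right) == 0) {
    stop("cluster_spec: both clusters must contain at least one channel")
  }
  if (length(intersect(left, right)) > 0) {
    stop("cluster_spec: left and right clusters must be disjoint")
  }
  structure(list(left = left, right = right), class = "cluster_spec")
}

#' @export
print.cluster_spec <- function(x, ...) {
  cat("Frontal clusters\n")
  cat("  left : ", paste(x$left, collapse = ", "), "\n", sep = "")
  cat("  right: ", paste(x$right, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# internal: assert that every cluster channel exists in a montage
check_clusters_present <- function(clusters, channel_labels) {
  missing <- setdiff(c(clusters$left, clusters$right), channel_labels)
  if (length(missing) > 0) {
    stop("cluster channels absent from montage: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}
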