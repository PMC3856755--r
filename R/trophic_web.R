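#' Binary plant x herbivore interaction web with a knowability mask
#'
#' A `trophic_web` holds the observed feeding links between plants (rows) and
#' butterflies (columns) together with a co-occurrence mask: a cell is
#' "knowable" only if the pair of species was recorded at the same site at
#' least once. Cells with `mask == 0` carry no information and never enter
#' any likelihood.
#'
#' @param links binary matrix, `links[i, j] = 1` if butterfly `j` (as a
#'   caterpillar) was recorded feeding on plant `i`.
#' @param mask binary matrix of the same shape; `1` marks pairs whose link
#'   status is knowable (co-occurring at least once). Defaults to all ones.
#' @param plant_ids,butterfly_ids species labels; default to dimnames of
#'   `links`.
#' @return an object of class `trophic_web` with elements `links`, `mask`,
#'   `plant_ids`, `butterfly_ids`.
#' @examples
#' w <- trophic_web(matrix(c(1, 0, 0, 1), 2, 2,
#'   dimnames = list(c("P1", "P2"), c("B1", "B2"))))
#' w
#' @export
trophic_web <- function(links, mask = NULL, plant_ids = NULL,
                        butterfly_ids = NULL) {
  links <- as.matrix(links)
  if (is.null(mask)) mask <- matrix(1L, nrow(links), ncol(links))
  mask <- as.matrix(mask)
  if (!all(dim(links) == dim(mask)))
    stopf("links (%dx%d) and mask (%dx%d) must have identical shape",
          nrow(links), ncol(links), nrow(mask), ncol(mask))
  if (!all(links %in% c(0, 1)) || !all(mask %in% c(0, 1)))
    stopf("links and mask entries must be 0/1")
  plant_ids <- plant_ids %||% rownames(links) %||%
    sprintf("plant_%02d", seq_len(nrow(links)))
  butterfly_ids <- butterfly_ids %||% colnames(links) %||%
    sprintf("butterfly_%02d", seq_len(ncol(links)))
  if (length(plant_ids) != nrow(links) ||
      length(butterfly_ids) != ncol(links))
    stopf("species label lengths do not match matrix shape")
  if (anyDuplicated(plant_ids) || anyDuplicated(butterfly_ids))
    stopf("species labels must be unique")
  storage.mode(links) <- "integer"
  storage.mode(mask) <- "integer"
  dimnames(links) <- dimnames(mask) <- list(plant_ids, butterfly_ids)
  structure(
    list(links = links, mask = mask, plant_ids = plant_ids,
         butterfly_ids = butterfly_ids),
    class = "trophic_web")
}

#' @export
print.trophic_web <- function(x, ...) {
  kn <- sum(x$mask)
  cat(sprintf("Trophic web: %d plants x %d butterflies\n",
              nrow(x$links), ncol(x$links)))
  cat(sprintf("  knowable pairs: %d of %d (%.1f%% masked out)\n",
              kn, length(x$mask), 100 * (1 - kn / length(x$mask))))
  cat(sprintf("  observed links: %d (%.1f%% of knowable pairs)\n",
              sum(x$links * x$mask),
              if (kn > 0) 100 * sum(x$links * x$mask) / kn else 0))
  invisible(x)
}

#' Co-occurrence knowability mask from site occupancy tables
#'
#' A plant-butterfly pair is knowable (`z_ij = 1`) if and only if at least one
#' site holds both species. Masked pairs are excluded from the link-model
#' likelihood.
#'
#' @param plant_occurrences site x plant 0/1 matrix (sites as rownames).
#' @param butterfly_occurrences site x butterfly 0/1 matrix over the same
#'   sites, in the same site order.
#' @return integer plants x butterflies 0/1 matrix.
#' @export
compute_cooccurrence_mask <- function(plant_occurrences,
                                      butterfly_occurrences) {
  p <- as.matrix(plant_occurrences)
  b <- as.matrix(butterfly_occurrences)
  if (nrow(p) != nrow(b))
    stopf("occurrence tables cover different site sets (%d vs %d sites)",
          nrow(p), nrow(b))
  if (!is.null(rownames(p)) && !is.null(rownames(b)) &&
      !identical(rownames(p), rownames(b)))
    stopf("occurrence tables must share the same site index")
  if (!all(p %in% c(0, 1)) || !all(b %in% c(0, 1)))
    stopf("occurrence tables must be 0/1")
  z <- (crossprod(p, b) > 0) * 1L
  dimnames(z) <- list(colnames(p), colnames(b))
  z
}

#' Read / write a trophic web as CSV
#'
#' Plants as rows, butterflies as columns, species labels in the header row
#' and first column, values 0/1. The mask uses the same layout.
#'
#' @param path CSV file of links.
#' @param mask_path optional CSV file of the knowability mask.
#' @return a [trophic_web].
#' @export
read_trophic_web <- function(path, mask_path = NULL) {
  links <- as.matrix(utils::read.csv(path, row.names = 1, check.names = FALSE))
  mask <- if (!is.null(mask_path))
    as.matrix(utils::read.csv(mask_path, row.names = 1, check.names = FALSE))
  trophic_web(links, mask)
}

#' @rdname read_trophic_web
#' @param web a [trophic_web].
#' @export
write_trophic_web <- function(web, path, mask_path = NULL) {
  utils::write.csv(web$links, path)
  if (!is.null(mask_path)) utils::write.csv(web$mask, mask_path)
  invisible(path)
}
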