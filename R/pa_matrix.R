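#' Validate a presence-absence matrix
#'
#' Checks the invariants of a species-by-sites occupancy matrix: all cells
#' are 0 or 1, species and site labels are unique, and no species row or
#' site column is entirely empty (absence is data here, but a species never
#' recorded anywhere, or a site with no species, indicates a malformed
#' input rather than a meaningful zero).
#'
#' @param x A numeric matrix with species as rownames and sites as
#'   colnames.
#' @return `x`, invisibly reclassed as `pa_matrix`, if valid; otherwise an
#'   error naming the offending rows/columns/cells.
#' @export
validate_pa_matrix <- function(x) {
  if (!is.matrix(x)) stop("presence-absence input must be a matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop("presence-absence matrix must have species rownames and site colnames")
  if (anyDuplicated(rownames(x)))
    stop("duplicate species labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop("duplicate site labels: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) {
    bad <- which(is.na(x), arr.ind = TRUE)[1, ]
    stop("missing cell at species '", rownames(x)[bad[1]], "', site '",
         colnames(x)[bad[2]], "': absences must be explicit 0s")
  }
  off <- which(!(x == 0 | x == 1), arr.ind = TRUE)
  if (nrow(off) > 0) {
    stop("non-binary cell(s): ",
         paste(sprintf("[%s, %s] = %s", rownames(x)[off[, 1]],
                       colnames(x)[off[, 2]], x[off]), collapse = "; "))
  }
  empty_sp <- rownames(x)[rowSums(x) == 0]
  if (length(empty_sp) > 0)
    stop("species with no occurrences: ", paste(empty_sp, collapse = ", "))
  empty_site <- colnames(x)[colSums(x) == 0]
  if (length(empty_site) > 0)
    stop("sites with no species: ", paste(empty_site, collapse = ", "))
  storage.mode(x) <- "integer"
  class(x) <- c("pa_matrix", class(unclass(x)))
  invisible(x)
}

#' Construct a presence-absence matrix
#'
#' @param x A 0/1 matrix, species in rows, sites in columns.
#' @param species,sites Optional label vectors overriding the dimnames.
#' @return A validated `pa_matrix`.
#' @export
pa_matrix <- function(x, species = rownames(x), sites = colnames(x)) {
  x <- as.matrix(x)
  rownames(x) <- species
  colnames(x) <- sites
  validate_pa_matrix(x)
}

#' Read a presence-absence matrix from delimited text
#'
#' The canonical layout is a comma-separated table whose first row holds
#' the site (island) labels and whose first column holds the species
#' labels; every remaining cell is 0 or 1. A cell left blank is an error,
#' not an implicit absence.
#'
#' @param path File to read.
#' @param sep Field delimiter; `","` (default) or `"\t"`.
#' @return A validated `pa_matrix` (species x sites).
#' @export
read_presence_absence <- function(path, sep = ",") {
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           stringsAsFactors = FALSE, colClasses = "character",
                           comment.char = "", quote = "\"")
  if (ncol(raw) < 2) stop("expected species label column plus >=1 site column")
  species <- raw[[1]]
  cells <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells),
                                 dimnames = list(species, colnames(cells))))
  bad <- which(is.na(num) | !(num == 0 | num == 1), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-binary cell(s) in ", path, ": ",
         paste(sprintf("species '%s', site '%s' (value '%s')",
                       species[bad[, 1]], colnames(cells)[bad[, 2]],
                       cells[bad]), collapse = "; "))
  }
  validate_pa_matrix(num)
}

#' Write a presence-absence matrix to delimited text
#'
#' Inverse of [read_presence_absence()]: the written file round-trips
#' cell-for-cell.
#'
#' @param x A `pa_matrix`.
#' @param path Output file.
#' @param sep Field delimiter.
#' @export
write_presence_absence <- function(x, path, sep = ",") {
  df <- data.frame(species = rownames(x), unclass(x), check.names = FALSE)
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @export
print.pa_matrix <- function(x, ...) {
  cat("Presence-absence matrix: ", nrow(x), " species x ", ncol(x),
      " sites (fill ", round(mean(x), 3), ")\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}
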