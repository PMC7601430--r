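#' Construct a validated pedigree
#'
#' Builds a pedigree object from animal/sire/dam identifier vectors. Unknown
#' parents are coded as `NA`, `""` or `"0"`. Any parent named but not listed
#' as an animal is completed as a founder record. The pedigree is checked for
#' duplicate identifiers and cycles, sorted so that parents precede their
#' offspring, and each animal is assigned a generation number (founders are
#' generation 0, otherwise 1 + the oldest parent's generation).
#'
#' @param animal character vector of animal ids.
#' @param sire character vector of sire ids (same length), unknown as above.
#' @param dam character vector of dam ids (same length), unknown as above.
#' @return A `data.frame` of class `"pedigree"` with columns `animal`, `sire`,
#'   `dam` (`NA` = unknown parent) and `generation`, in topological order.
#' @examples
#' ped <- pedigree(c("s", "d", "o"), c(NA, NA, "s"), c(NA, NA, "d"))
#' ped$generation
#' @export
pedigree <- function(animal, sire = NA, dam = NA) {
  animal <- as.character(animal)
  sire <- clean_parent_id(rep_len(as.character(sire), length(animal)))
  dam <- clean_parent_id(rep_len(as.character(dam), length(animal)))
  if (anyNA(animal) || any(animal == ""))
    stop("animal ids must be non-missing, non-empty strings")
  if (anyDuplicated(animal))
    stop("duplicate animal ids: ", paste(unique(animal[duplicated(animal)]),
                                         collapse = ", "))
  # complete parents that never appear as animals: they become founders
  parents <- setdiff(c(sire, dam), c(animal, NA))
  if (length(parents)) {
    animal <- c(parents, animal)
    sire <- c(rep(NA_character_, length(parents)), sire)
    dam <- c(rep(NA_character_, length(parents)), dam)
  }
  n <- length(animal)
  idx <- seq_len(n)
  names(idx) <- animal
  si <- unname(idx[sire])
  di <- unname(idx[dam])

  # Kahn topological sort; failure to exhaust the list means a cycle
  gen <- rep.int(NA_integer_, n)
  order_out <- integer(n)
  remaining <- rep(TRUE, n)
  filled <- 0L
  repeat {
    # a node is ready when each known parent is already placed
    ready <- which(remaining &
                     (is.na(si) | !remaining[ifelse(is.na(si), 1L, si)]) &
                     (is.na(di) | !remaining[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) break
    pg <- pmax(ifelse(is.na(si[ready]), -1L, gen[ifelse(is.na(si[ready]), 1L, si[ready])]),
               ifelse(is.na(di[ready]), -1L, gen[ifelse(is.na(di[ready]), 1L, di[ready])]))
    gen[ready] <- pg + 1L
    order_out[filled + seq_along(ready)] <- ready
    filled <- filled + length(ready)
    remaining[ready] <- FALSE
    if (filled == n) break
  }
  if (filled < n)
    stop("pedigree contains a cycle involving: ",
         paste(utils::head(animal[remaining], 5), collapse = ", "))
  ord <- order_out
  out <- data.frame(animal = animal[ord], sire = sire[ord], dam = dam[ord],
                    generation = gen[ord], stringsAsFactors = FALSE)
  class(out) <- c("pedigree", "data.frame")
  out
}

clean_parent_id <- function(x) {
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "animals,",
      sum(is.na(x$sire) & is.na(x$dam)), "founders,",
      max(x$generation) + 1L, "generation(s)\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}

is_pedigree <- function(x) inherits(x, "pedigree")

stopifnot_pedigree <- function(x) {
  if (!is_pedigree(x)) stop("expected a 'pedigree' object; see ?pedigree")
  invisible(x)
}

#' Read / write a pedigree as CSV
#'
#' The file has columns `animal,sire,dam`; `"0"` or an empty field marks an
#' unknown parent.
#'
#' @param file path to a CSV file.
#' @return `read_pedigree` returns a [pedigree] object.
#' @export
read_pedigree <- function(file) {
  df <- utils::read.csv(file, colClasses = "character")
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree CSV must have columns: ", paste(need, collapse = ", "))
  pedigree(df$animal, df$sire, df$dam)
}

#' @param ped a [pedigree] object.
#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, file) {
  stopifnot_pedigree(ped)
  out <- as.data.frame(ped)[, c("animal", "sire", "dam")]
  out$sire[is.na(out$sire)] <- "0"
  out$dam[is.na(out$dam)] <- "0"
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
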