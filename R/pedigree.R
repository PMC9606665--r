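#' Construct and validate a pedigree
#'
#' A pedigree is a data frame with columns \code{id}, \code{sire} and
#' \code{dam}, one row per individual, ordered so that parents appear
#' before their offspring. Unknown parents are coded \code{0} (or
#' \code{NA}, which is converted to \code{0}).
#'
#' @param id vector of individual identifiers (unique).
#' @param sire vector of sire identifiers; 0/NA = unknown.
#' @param dam vector of dam identifiers; 0/NA = unknown.
#' @param ... further per-individual columns (e.g. \code{sex},
#'   \code{generation}) carried along unchecked.
#'
#' @return A \code{data.frame} of class \code{ped} with character
#'   \code{id}, \code{sire}, \code{dam} columns (\code{"0"} = unknown).
#'
#' @details Validation enforces unique ids, no self-parenting, and the
#' topological property that every known parent occurs as an individual
#' earlier in the order (which also rules out ancestry cycles).
#'
#' @examples
#' ped <- pedigree(id = c(1, 2, 3), sire = c(0, 0, 1), dam = c(0, 0, 2))
#' @export
pedigree <- function(id, sire, dam, ...) {
  id   <- as.character(id)
  sire <- as.character(sire)
  dam  <- as.character(dam)
  sire[is.na(sire)] <- "0"
  dam[is.na(dam)]   <- "0"
  ped <- data.frame(id = id, sire = sire, dam = dam, ...,
                    stringsAsFactors = FALSE)
  validate_pedigree(ped)
  class(ped) <- c("ped", "data.frame")
  ped
}

validate_pedigree <- function(ped) {
  if (anyDuplicated(ped$id))
    stop("pedigree ids must be unique; duplicated: ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  if (any(ped$id == "0"))
    stop("'0' is reserved for unknown parents and cannot be an id")
  if (any(ped$sire == ped$id & ped$sire != "0") ||
      any(ped$dam == ped$id & ped$dam != "0"))
    stop("an individual cannot be its own parent")
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  for (col in c("sire", "dam")) {
    par <- ped[[col]]
    known <- par != "0"
    miss <- known & !(par %in% ped$id)
    if (any(miss))
      stop("unknown-parent code or unordered pedigree: ", col, "(s) ",
           paste(unique(par[miss]), collapse = ", "),
           " do not appear as individuals")
    bad <- known & pos[par] >= pos[ped$id]
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      stop("pedigree is not topologically ordered: ", col, " of ",
           paste(ped$id[bad], collapse = ", "),
           " appears at or after the individual itself")
  }
  invisible(ped)
}

#' Read a pedigree from CSV
#'
#' Expects a header with columns \code{id}, \code{sire}, \code{dam};
#' \code{0} or empty fields denote unknown parents.
#'
#' @param file path to a CSV file.
#' @return A \code{ped} object (see [pedigree()]).
#' @export
read_pedigree <- function(file) {
  df <- utils::read.csv(file, colClasses = "character",
                        strip.white = TRUE)
  names(df) <- tolower(names(df))
  need <- c("id", "sire", "dam")
  if (!all(need %in% names(df)))
    stop("pedigree file must have columns id, sire, dam")
  df$sire[df$sire == ""] <- "0"
  df$dam[df$dam == ""]   <- "0"
  do.call(pedigree, df[c(need, setdiff(names(df), need))])
}

#' Write a pedigree to CSV
#'
#' @param ped a \code{ped} object.
#' @param file output path.
#' @export
write_pedigree <- function(ped, file) {
  utils::write.csv(as.data.frame(ped), file, row.names = FALSE,
                   quote = FALSE)
}

# index of each parent in ped order; 0 for unknown
parent_index <- function(ped) {
  pos <- seq_len(nrow(ped))
  names(pos) <- ped$id
  s <- ifelse(ped$sire == "0", 0L, pos[ped$sire])
  d <- ifelse(ped$dam == "0", 0L, pos[ped$dam])
  list(s = unname(s), d = unname(d))
}
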