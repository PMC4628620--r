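#' Construct and validate a pedigree
#'
#' Builds a `pedigree` object from individual/father/mother/sex records,
#' checking the structural rules the polygenic model relies on: every named
#' parent must itself be a pedigree member, parents come in pairs (an
#' individual has either both parents or neither -- founders), and the parent
#' graph must be acyclic.  Individuals are reordered topologically so that
#' every parent precedes all of its children; the kinship recursion requires
#' this order.
#'
#' @param id character vector of individual identifiers (unique, non-missing).
#' @param father,mother character vectors of parental identifiers;
#'   `missing_code` (or `NA`) marks an unknown parent.
#' @param sex sex codes: `1`/`"male"`, `2`/`"female"`, `0`/`"unknown"`.
#'   Carried for bookkeeping; autosomal kinship does not use it.
#' @param missing_code token encoding a missing parent on file (default `"0"`,
#'   the PLINK convention).
#'
#' @return A `pedigree`: a `data.frame` with columns `id`, `father`, `mother`
#'   (`NA` for founders) and `sex` (factor male/female/unknown), rows in
#'   topological order, with attribute `n_founders`.
#'
#' @examples
#' ped <- pedigree(id     = c("C", "F", "M"),
#'                 father = c("F", "0", "0"),
#'                 mother = c("M", "0", "0"),
#'                 sex    = c(1, 1, 2))
#' ped
#' @export
pedigree <- function(id, father, mother, sex = NULL, missing_code = "0") {
  id <- as.character(id)
  father <- as.character(father)
  mother <- as.character(mother)
  n <- length(id)
  if (length(father) != n || length(mother) != n)
    stop("id, father and mother must have equal length")
  if (anyNA(id) || any(id == missing_code))
    stop("individual ids must be non-missing and distinct from the missing code")
  if (anyDuplicated(id))
    stop("duplicated individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  father[is.na(father) | father == missing_code] <- NA_character_
  mother[is.na(mother) | mother == missing_code] <- NA_character_

  half <- xor(is.na(father), is.na(mother))
  if (any(half))
    stop("half-specified parents (one parent named, the other missing) for: ",
         paste(id[half], collapse = ", "),
         "; the model needs both parents or neither")
  known <- c(father, mother)
  known <- known[!is.na(known)]
  absent <- setdiff(unique(known), id)
  if (length(absent))
    stop("parent(s) referenced but absent from the pedigree: ",
         paste(absent, collapse = ", "))

  if (is.null(sex)) sex <- rep("unknown", n)
  sex <- decode_sex(sex)

  ord <- topo_order(id, father, mother)
  ped <- data.frame(id = id[ord], father = father[ord], mother = mother[ord],
                    sex = sex[ord], stringsAsFactors = FALSE)
  attr(ped, "n_founders") <- sum(is.na(ped$father))
  class(ped) <- c("pedigree", "data.frame")
  ped
}

decode_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- rep(NA_character_, length(s))
  out[s %in% c("1", "m", "male")] <- "male"
  out[s %in% c("2", "f", "female")] <- "female"
  out[s %in% c("0", "u", "unknown", "na") | is.na(s)] <- "unknown"
  if (anyNA(out))
    stop("unrecognized sex code(s): ", paste(unique(s[is.na(out)]), collapse = ", "))
  factor(out, levels = c("male", "female", "unknown"))
}

# Kahn's algorithm on the parent->child graph; a leftover node means a cycle.
topo_order <- function(id, father, mother) {
  n <- length(id)
  idx <- seq_len(n)
  names(idx) <- id
  fi <- unname(idx[father])
  mi <- unname(idx[mother])
  indeg <- integer(n)
  indeg[!is.na(fi)] <- indeg[!is.na(fi)] + 1L
  indeg[!is.na(mi)] <- indeg[!is.na(mi)] + 1L
  children <- vector("list", n)
  for (i in seq_len(n)) {
    if (!is.na(fi[i])) children[[fi[i]]] <- c(children[[fi[i]]], i)
    if (!is.na(mi[i])) children[[mi[i]]] <- c(children[[mi[i]]], i)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (ch in children[[v]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < n) {
    on_cycle <- setdiff(seq_len(n), ord)
    stop("pedigree contains a cycle (an individual is its own ancestor); ",
         "involved: ", paste(id[on_cycle[seq_len(min(5, length(on_cycle)))]],
                             collapse = ", "))
  }
  ord
}

#' Validate raw pedigree rows
#'
#' Thin wrapper around [pedigree()] for data read from file: takes a
#' data.frame with `id`/`father`/`mother`(/`sex`) columns and returns a
#' validated, topologically ordered `pedigree`.
#'
#' @param records data.frame of raw rows.
#' @inheritParams pedigree
#' @return A `pedigree` object.
#' @export
validate_pedigree <- function(records, missing_code = "0") {
  stopifnot(is.data.frame(records))
  need <- c("id", "father", "mother")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("pedigree records lack column(s): ", paste(miss, collapse = ", "))
  sex <- if ("sex" %in% names(records)) records$sex else NULL
  pedigree(records$id, records$father, records$mother, sex,
           missing_code = missing_code)
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d individuals (%d founders, %d non-founders)\n",
              nrow(x), attr(x, "n_founders"), nrow(x) - attr(x, "n_founders")))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

#' @export
summary.pedigree <- function(object, ...) {
  fo <- is.na(object$father)
  structure(list(n = nrow(object), n_founders = sum(fo),
                 sex = table(object$sex)),
            class = "summary.pedigree")
}

#' @export
print.summary.pedigree <- function(x, ...) {
  cat(sprintf("%d individuals, %d founders\n", x$n, x$n_founders))
  print(x$sex)
  invisible(x)
}

#' Read / write a PLINK-style .fam pedigree file
#'
#' Whitespace-delimited `FID IID FATHER MOTHER SEX [PHENOTYPE]`; the family id
#' and any phenotype column are ignored, and a header line is detected
#' automatically (a first line whose fifth field is not a sex code).  Files
#' with only `id father mother sex` columns are also accepted.
#'
#' @param path file path.
#' @param missing_code missing-parent token (default `"0"`).
#' @return [read_fam()]: a `pedigree`.  [write_fam()]: the path, invisibly.
#' @export
read_fam <- function(path, missing_code = "0") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty pedigree file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4))
    stop("malformed pedigree line ", which(nf < 4)[1], ": fewer than 4 fields")
  six <- nf[1] >= 5
  first <- fields[[1]]
  sex_field <- if (six) first[5] else first[4]
  has_header <- !(sex_field %in% c("0", "1", "2")) &&
    is.na(suppressWarnings(as.numeric(sex_field)))
  if (has_header) fields <- fields[-1]
  m <- do.call(rbind, fields)
  if (six) {
    pedigree(m[, 2], m[, 3], m[, 4], m[, 5], missing_code = missing_code)
  } else {
    pedigree(m[, 1], m[, 2], m[, 3], m[, 4], missing_code = missing_code)
  }
}

#' @rdname read_fam
#' @param ped a `pedigree`.
#' @param fid family-id token written in the first column.
#' @export
write_fam <- function(ped, path, fid = "FAM1", missing_code = "0") {
  stopifnot(inherits(ped, "pedigree"))
  f <- ifelse(is.na(ped$father), missing_code, ped$father)
  m <- ifelse(is.na(ped$mother), missing_code, ped$mother)
  s <- c(male = "1", female = "2", unknown = "0")[as.character(ped$sex)]
  writeLines(paste(fid, ped$id, f, m, s, "-9", sep = " "), path)
  invisible(path)
}
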