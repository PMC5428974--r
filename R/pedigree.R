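#' Construct a pedigree
#'
#' A pedigree is a data frame with one row per member and columns `id`,
#' `sex` (`"male"`/`"female"`), `affected` (logical), `father`, `mother`
#' (member ids or `NA` for founders). Parent links must be acyclic and
#' refer to existing members of the stated sex.
#'
#' @param id character vector of unique member ids.
#' @param sex character vector, `"male"` or `"female"`.
#' @param affected logical vector of affection status.
#' @param father,mother character vectors of parent ids (`NA` = founder).
#' @return An object of class `pedigree` (a validated data frame).
#' @examples
#' trio <- pedigree(
#'   id = c("F", "M", "C"),
#'   sex = c("male", "female", "male"),
#'   affected = c(FALSE, FALSE, TRUE),
#'   father = c(NA, NA, "F"),
#'   mother = c(NA, NA, "M")
#' )
#' trio
#' @export
pedigree <- function(id, sex, affected, father = NA_character_,
                     mother = NA_character_) {
  df <- data.frame(
    id = as.character(id),
    sex = as.character(sex),
    affected = as.logical(affected),
    father = as.character(rep_len(father, length(id))),
    mother = as.character(rep_len(mother, length(id))),
    stringsAsFactors = FALSE
  )
  validate_pedigree(df)
}

validate_pedigree <- function(df) {
  if (anyDuplicated(df$id)) {
    stop("duplicate pedigree member id(s): ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  bad_sex <- !df$sex %in% c("male", "female")
  if (any(bad_sex)) {
    stop("invalid sex for member(s): ", paste(df$id[bad_sex], collapse = ", "))
  }
  for (col in c("father", "mother")) {
    p <- df[[col]]
    unknown <- !is.na(p) & !p %in% df$id
    if (any(unknown)) {
      stop("unknown ", col, " id(s): ", paste(unique(p[unknown]), collapse = ", "))
    }
    self <- !is.na(p) & p == df$id
    if (any(self)) {
      stop("pedigree cycle: member(s) ", paste(df$id[self], collapse = ", "),
           " listed as own ", col)
    }
  }
  wrong_f <- !is.na(df$father) & df$sex[match(df$father, df$id)] != "male"
  wrong_m <- !is.na(df$mother) & df$sex[match(df$mother, df$id)] != "female"
  if (any(wrong_f) || any(wrong_m)) {
    stop("parent sex inconsistent with father/mother role")
  }
  # cycle detection: depth must be computable for every member
  depth <- pedigree_depth(df)
  if (anyNA(depth)) {
    stop("pedigree cycle detected involving member(s): ",
         paste(df$id[is.na(depth)], collapse = ", "))
  }
  structure(df, class = c("pedigree", "data.frame"))
}

# generation depth (founders = 0); NA marks members stuck in a parent cycle
pedigree_depth <- function(df) {
  n <- nrow(df)
  depth <- ifelse(is.na(df$father) & is.na(df$mother), 0, NA_real_)
  fi <- match(df$father, df$id)
  mi <- match(df$mother, df$id)
  for (iter in seq_len(n + 1L)) {
    todo <- which(is.na(depth))
    if (!length(todo)) break
    for (i in todo) {
      dp <- c(if (!is.na(fi[i])) depth[fi[i]] else 0,
              if (!is.na(mi[i])) depth[mi[i]] else 0)
      if (!anyNA(dp)) depth[i] <- max(dp) + 1
    }
  }
  depth
}

#' @export
print.pedigree <- function(x, ...) {
  cat(sprintf("Pedigree: %d members (%d affected, %d founders)\n",
              nrow(x), sum(x$affected),
              sum(is.na(x$father) & is.na(x$mother))))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Read a 6-column PED file
#'
#' Standard whitespace-delimited PED: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female), phenotype (2 = affected,
#' 1 = unaffected, 0/-9 = unknown, treated as unaffected for filtering).
#' `0` in a parent column marks a founder.
#'
#' @param path path to the PED file.
#' @return A [pedigree] object.
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 6) stop("PED file must have at least 6 columns: ", path)
  sex_code <- tab[[5]]
  if (!all(sex_code %in% c("1", "2"))) {
    stop("sex code outside {1,2} in PED file: ",
         paste(unique(sex_code[!sex_code %in% c("1", "2")]), collapse = ", "))
  }
  pedigree(
    id = tab[[2]],
    sex = c("1" = "male", "2" = "female")[sex_code],
    affected = tab[[6]] == "2",
    father = ifelse(tab[[3]] == "0", NA_character_, tab[[3]]),
    mother = ifelse(tab[[4]] == "0", NA_character_, tab[[4]])
  )
}

#' Write a pedigree as a 6-column PED file
#'
#' @param ped a [pedigree] object.
#' @param path output path.
#' @param family family id written in column 1.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(ped, path, family = "FAM1") {
  out <- data.frame(
    fam = family,
    id = ped$id,
    father = ifelse(is.na(ped$father), "0", ped$father),
    mother = ifelse(is.na(ped$mother), "0", ped$mother),
    sex = ifelse(ped$sex == "male", "1", "2"),
    phe = ifelse(ped$affected, "2", "1")
  )
  utils::write.table(out, path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Kinship coefficient between two pedigree members
#'
#' Standard recursive kinship: phi(a, a) = (1 + F_a) / 2 where F_a is the
#' inbreeding coefficient of a, and phi(a, b) averages over the deeper
#' member's parents. Founders are assumed unrelated and non-inbred.
#'
#' @param ped a [pedigree] object.
#' @param a,b member ids.
#' @return The kinship coefficient (probability that random alleles drawn
#'   from a and b are identical by descent).
#' @examples
#' fam <- first_cousin_pedigree()
#' kinship_coefficient(fam, "father", "mother")  # first cousins: 1/16
#' @export
kinship_coefficient <- function(ped, a, b) {
  stopifnot(a %in% ped$id, b %in% ped$id)
  depth <- pedigree_depth(ped)
  names(depth) <- ped$id
  fa <- stats::setNames(ped$father, ped$id)
  mo <- stats::setNames(ped$mother, ped$id)
  memo <- new.env(parent = emptyenv())
  phi <- function(x, y) {
    key <- paste(sort(c(x, y)), collapse = "\r")
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- if (x == y) {
      if (is.na(fa[[x]]) || is.na(mo[[x]])) 0.5
      else 0.5 * (1 + phi(fa[[x]], mo[[x]]))
    } else {
      # recurse on the member further from the founders
      if (depth[[x]] < depth[[y]]) { tmp <- x; x <- y; y <- tmp }
      if (is.na(fa[[x]]) && is.na(mo[[x]])) 0
      else 0.5 * (phi_or0(fa[[x]], y, phi) + phi_or0(mo[[x]], y, phi))
    }
    memo[[key]] <- val
    val
  }
  phi(a, b)
}

phi_or0 <- function(p, y, phi) if (is.na(p)) 0 else phi(p, y)

#' Inbreeding coefficient of a pedigree member
#'
#' Equals the kinship coefficient of the member's parents (0 for founders
#' or members with an unknown parent).
#'
#' @inheritParams kinship_coefficient
#' @param id member id.
#' @export
inbreeding_coefficient <- function(ped, id) {
  stopifnot(id %in% ped$id)
  row <- ped[ped$id == id, ]
  if (is.na(row$father) || is.na(row$mother)) return(0)
  kinship_coefficient(ped, row$father, row$mother)
}

#' Ids of affected members
#' @inheritParams kinship_coefficient
#' @return Character vector of affected member ids.
#' @export
affected_ids <- function(ped) ped$id[ped$affected]
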