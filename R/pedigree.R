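#' Construct a trio pedigree
#'
#' A trio pedigree holds the three sample identifiers of a
#' proband/mother/father trio and the proband's sex, which is required before
#' any X-chromosome genotype can be interpreted (hemizygosity in males).
#'
#' @param proband_id,mother_id,father_id Sample identifiers; must be three
#'   distinct non-empty strings matching the VCF header columns.
#' @param proband_sex One of `"male"`, `"female"`, `"unknown"`.
#' @param family_id Family label (free text).
#' @return An object of class `trio_pedigree`.
#' @export
#' @examples
#' trio_pedigree("P1", "M1", "F1", proband_sex = "male")
trio_pedigree <- function(proband_id, mother_id, father_id,
                          proband_sex = c("unknown", "male", "female"),
                          family_id = "FAM1") {
  proband_sex <- match.arg(proband_sex)
  ids <- c(proband_id, mother_id, father_id)
  if (!is.character(ids) || length(ids) != 3L || any(!nzchar(ids)) || anyNA(ids)) {
    stop("proband, mother and father ids must be non-empty strings")
  }
  if (anyDuplicated(ids)) {
    stop("format error: pedigree sample ids must be distinct (got ",
         paste(ids, collapse = ", "), ")")
  }
  structure(
    list(family_id = family_id,
         proband_id = proband_id,
         mother_id = mother_id,
         father_id = father_id,
         proband_sex = proband_sex),
    class = "trio_pedigree"
  )
}

#' @export
print.trio_pedigree <- function(x, ...) {
  cat("Trio pedigree [", x$family_id, "]\n", sep = "")
  cat("  proband: ", x$proband_id, " (", x$proband_sex, ")\n", sep = "")
  cat("  mother:  ", x$mother_id, "\n", sep = "")
  cat("  father:  ", x$father_id, "\n", sep = "")
  invisible(x)
}

#' Read the first complete trio from a PED file
#'
#' Parses a standard 6-column PED file (family, sample, father, mother, sex,
#' phenotype) and returns the first sample that has both parent ids set, as a
#' [trio_pedigree()]. Sex is decoded from column 5 (1 = male, 2 = female,
#' anything else = unknown).
#'
#' @param path Path to a whitespace-delimited PED file without header.
#' @return A `trio_pedigree`.
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(ped) < 5L) {
    stop("format error: PED file must have at least 5 columns")
  }
  names(ped)[1:5] <- c("family_id", "sample_id", "father_id", "mother_id", "sex")
  if (anyDuplicated(ped$sample_id)) {
    stop("format error: duplicate sample id in PED: ",
         paste(unique(ped$sample_id[duplicated(ped$sample_id)]), collapse = ", "))
  }
  complete <- nzchar(ped$father_id) & ped$father_id != "0" &
    nzchar(ped$mother_id) & ped$mother_id != "0"
  if (!any(complete)) {
    stop("incomplete trio: no PED sample has both parent ids set")
  }
  row <- ped[which(complete)[1L], ]
  sex <- switch(row$sex, "1" = "male", "2" = "female", "unknown")
  trio_pedigree(row$sample_id, row$mother_id, row$father_id,
                proband_sex = sex, family_id = row$family_id)
}

#' Write a trio pedigree as a 6-column PED file
#'
#' Emits one row per trio member (proband with both parents set, parents as
#' founders). Sex is written as 1/2/0 in column 5; phenotype column 6 is set
#' to 2 (affected) for the proband and 1 otherwise.
#'
#' @param pedigree A [trio_pedigree()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(pedigree, path) {
  stopifnot(inherits(pedigree, "trio_pedigree"))
  sex_code <- switch(pedigree$proband_sex, male = "1", female = "2", "0")
  rows <- c(
    paste(pedigree$family_id, pedigree$proband_id, pedigree$father_id,
          pedigree$mother_id, sex_code, "2"),
    paste(pedigree$family_id, pedigree$mother_id, "0", "0", "2", "1"),
    paste(pedigree$family_id, pedigree$father_id, "0", "0", "1", "1")
  )
  writeLines(rows, path)
  invisible(path)
}
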