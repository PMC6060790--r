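# Class schema: the classifier's class list with tumor/control categories and
# methylation-class-family membership.

#' Construct a class schema
#'
#' The schema enumerates the classifier's methylation classes, their category
#' (tumor or control tissue) and the methylation class families — named
#' groups of 2–6 closely related classes whose calibrated scores are summed
#' for decision making.
#'
#' @param classes Data.frame with columns `class`, `category`
#'   (`"tumor"`/`"control"`) and `family` (family name or `NA`/`""` for
#'   classes outside any family).
#' @return A `class_schema`: list with `classes` (the table, `family` as `NA`
#'   when absent) and `families` (named list of member-class vectors).
#' @export
class_schema <- function(classes) {
  need <- c("class", "category", "family")
  if (!all(need %in% names(classes))) {
    stop("schema table must have columns: ", paste(need, collapse = ", "))
  }
  classes$class <- as.character(classes$class)
  classes$category <- as.character(classes$category)
  classes$family <- as.character(classes$family)
  classes$family[!is.na(classes$family) & classes$family == ""] <- NA_character_
  if (anyDuplicated(classes$class)) stop("duplicate class names in schema")
  if (!all(classes$category %in% c("tumor", "control"))) {
    stop("category must be 'tumor' or 'control'")
  }
  fams <- split(classes$class[!is.na(classes$family)],
                classes$family[!is.na(classes$family)])
  sizes <- lengths(fams)
  if (any(sizes < 2 | sizes > 6)) {
    stop("families must have 2-6 member classes; offending: ",
         paste(names(fams)[sizes < 2 | sizes > 6], collapse = ", "))
  }
  structure(list(classes = classes[, need], families = fams),
            class = "class_schema")
}

#' Read a class schema file
#'
#' Structured-text (TSV) schema with columns `class`, `category`, `family`;
#' an editable flat file so updated classifier versions load without code
#' change.
#'
#' @param path Schema TSV path; `NULL` loads the bundled v11b4 schema
#'   (82 tumor classes, 9 control classes, 8 families).
#' @return A [class_schema()].
#' @export
read_class_schema <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "class_schema_v11b4.tsv",
                        package = "methylDx", mustWork = TRUE)
  }
  d <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  class_schema(d)
}

#' Write a class schema file
#'
#' @param schema A [class_schema()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_class_schema <- function(schema, path) {
  stopifnot(inherits(schema, "class_schema"))
  d <- schema$classes
  d$family[is.na(d$family)] <- ""
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.class_schema <- function(x, ...) {
  tab <- table(x$classes$category)
  cat(sprintf("class_schema: %d classes (%d tumor, %d control), %d families\n",
              nrow(x$classes), tab[["tumor"]],
              if ("control" %in% names(tab)) tab[["control"]] else 0L,
              length(x$families)))
  invisible(x)
}
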