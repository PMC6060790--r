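# Calibrated-score interpretation: validation, family sum rule, threshold
# ladder and report formatting.

#' Default decision thresholds
#'
#' The threshold ladder for calibrated scores: `classifiable` 0.9 (the
#' default cut-off a class or family score must reach), `borderline_floor`
#' 0.84 (the Youden-optimal cut-off on the reference cohort — scores in
#' `[0.84, 0.9)` may be accepted as valid if nothing else speaks against it),
#' `suggestive_floor` 0.5 (scores in `[0.5, 0.84)` only suggest a relation;
#' below 0.5 is generally discarded), `reporting_floor` 0.3 (only scores
#' above it are listed), and `subclass_cutoff` 0.5 (the member-class score
#' needed to name the most likely subclass within a classifiable family).
#'
#' @param classifiable,borderline_floor,suggestive_floor,reporting_floor,subclass_cutoff
#'   Override individual levels; the first four must be strictly decreasing.
#' @return Named list of thresholds.
#' @export
default_thresholds <- function(classifiable = 0.9, borderline_floor = 0.84,
                               suggestive_floor = 0.5, reporting_floor = 0.3,
                               subclass_cutoff = 0.5) {
  th <- list(classifiable = classifiable, borderline_floor = borderline_floor,
             suggestive_floor = suggestive_floor,
             reporting_floor = reporting_floor,
             subclass_cutoff = subclass_cutoff)
  ladder <- c(th$classifiable, th$borderline_floor, th$suggestive_floor,
              th$reporting_floor)
  if (any(diff(ladder) >= 0)) {
    stop("thresholds must be strictly decreasing: ",
         "classifiable > borderline_floor > suggestive_floor > reporting_floor")
  }
  th
}

#' Construct and validate a calibrated score vector
#'
#' A calibrated score vector assigns one class-membership probability to
#' every schema class; the probabilities must sum to 1 (tolerance `1e-6`).
#' Vectors outside tolerance are rejected, not silently renormalized.
#'
#' @param scores Named numeric vector, class name to probability.
#' @param schema A [class_schema()].
#' @param sample_id Sample identifier.
#' @param tol Sum-to-one tolerance (default `1e-6`).
#' @return A `score_vector`: list with `sample_id` and `scores` (ordered as
#'   in the schema).
#' @export
score_vector <- function(scores, schema, sample_id = "sample", tol = 1e-6) {
  stopifnot(inherits(schema, "class_schema"))
  cls <- schema$classes$class
  missing <- setdiff(cls, names(scores))
  if (length(missing) > 0) {
    stop("score vector missing class(es): ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (+%d more)", length(missing) - 5))
  }
  extra <- setdiff(names(scores), cls)
  if (length(extra) > 0) {
    stop("score vector has unknown class(es): ",
         paste(utils::head(extra, 5), collapse = ", "))
  }
  s <- as.numeric(scores[cls]); names(s) <- cls
  if (any(!is.finite(s)) || any(s < 0) || any(s > 1)) {
    stop("scores must lie in [0, 1]")
  }
  if (abs(sum(s) - 1) > tol) {
    stop(sprintf("scores sum to %.8f, not 1 (tolerance %g); not renormalizing",
                 sum(s), tol))
  }
  structure(list(sample_id = as.character(sample_id), scores = s),
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, ...) {
  top <- sort(x$scores, decreasing = TRUE)[1]
  cat(sprintf("score_vector: %s (%d classes, top: %s = %.3f)\n",
              x$sample_id, length(x$scores), names(top), top))
  invisible(x)
}

#' Family scores by the probability sum rule
#'
#' Since calibrated scores are probability estimates, the probability of
#' membership in a methylation class family is the exact sum of its member
#' class scores. Classes outside any family are unaffected (their class
#' score stands alone).
#'
#' @param v A [score_vector()].
#' @param schema A [class_schema()].
#' @return Named numeric vector, family name to summed probability.
#' @export
family_scores <- function(v, schema) {
  stopifnot(inherits(v, "score_vector"), inherits(schema, "class_schema"))
  vapply(schema$families, function(members) sum(v$scores[members]), numeric(1))
}

#' Apply the threshold ladder to a calibrated score vector
#'
#' The decision is driven by the best of the top class score and the top
#' family score:
#' \itemize{
#'   \item `>= classifiable` (0.9): classifiable. If only the family sum
#'     reaches the threshold the result is family-level
#'     (`classifiable_family`), and the most likely subclass is named when
#'     the best member class reaches `subclass_cutoff` (0.5); otherwise the
#'     class-level result is reported with family context attached.
#'   \item `[borderline_floor, classifiable)` ([0.84, 0.9)): `borderline` — a
#'     valid classification if nothing else strongly speaks against it.
#'   \item `[suggestive_floor, borderline_floor)` ([0.5, 0.84)): `suggestive`
#'     — a hint of relatedness that needs corroborating evidence.
#'   \item below `suggestive_floor`: `no_match`.
#' }
#' With `low_purity = TRUE` (low tumor-cell content, e.g. infiltration-zone
#' material) borderline and suggestive results carry an annotation that a
#' lower score may be accepted as an indication of a specific diagnosis.
#' When the control-tissue class scores sum to `reporting_floor` (0.3) or
#' more, the `control_elevated` flag is set — typical of low tumor content.
#'
#' @param v A [score_vector()].
#' @param schema A [class_schema()].
#' @param thresholds See [default_thresholds()].
#' @param low_purity Logical: sample known to have low tumor-cell content.
#' @return A `decision_report`: list with `sample_id`, `category`,
#'   `top_class`, `top_class_score`, `top_family`, `family_score`,
#'   `subclass`, `subclass_score`, `listed_scores` (class scores above the
#'   reporting floor, descending), `listed_family_scores`, `flags`, `notes`.
#' @export
decide <- function(v, schema, thresholds = default_thresholds(),
                   low_purity = FALSE) {
  stopifnot(inherits(v, "score_vector"), inherits(schema, "class_schema"))
  s <- v$scores
  fs <- family_scores(v, schema)
  top_class <- names(s)[which.max(s)]
  top_class_score <- unname(max(s))
  top_family <- if (length(fs)) names(fs)[which.max(fs)] else NA_character_
  top_family_score <- if (length(fs)) unname(max(fs)) else -Inf
  best <- max(top_class_score, top_family_score)

  th <- thresholds
  subclass <- NA_character_; subclass_score <- NA_real_
  notes <- character(0)
  if (best >= th$classifiable) {
    if (top_class_score >= th$classifiable) {
      category <- "classifiable_class"
      fam_of_top <- schema$classes$family[schema$classes$class == top_class]
      if (!is.na(fam_of_top) && fs[[fam_of_top]] >= th$classifiable) {
        notes <- c(notes, sprintf(
          "family context: %s (family score %.2f) also reaches the threshold",
          fam_of_top, fs[[fam_of_top]]))
      }
    } else {
      category <- "classifiable_family"
      members <- schema$families[[top_family]]
      bm <- members[which.max(s[members])]
      if (s[[bm]] >= th$subclass_cutoff) {
        subclass <- bm
        subclass_score <- unname(s[[bm]])
      } else {
        notes <- c(notes, sprintf(
          "no member class reaches the subclass cut-off of %.2f; family-level result only",
          th$subclass_cutoff))
      }
    }
  } else if (best >= th$borderline_floor) {
    category <- "borderline"
    notes <- c(notes,
               "score in the borderline band: a valid classification if nothing else strongly speaks against it")
  } else if (best >= th$suggestive_floor) {
    category <- "suggestive"
    notes <- c(notes,
               "score only suggests a relation to the class; seek corroborating evidence")
  } else {
    category <- "no_match"
  }

  flags <- character(0)
  control_sum <- sum(s[schema$classes$class[schema$classes$category == "control"]])
  if (control_sum >= th$reporting_floor) flags <- c(flags, "control_elevated")
  if (low_purity) {
    flags <- c(flags, "low_purity")
    if (category %in% c("borderline", "suggestive")) {
      notes <- c(notes,
                 "low tumor-cell content: a lower score may be accepted as an indication of a specific diagnosis")
    }
  }

  listed <- sort(s[s > th$reporting_floor], decreasing = TRUE)
  listed_fam <- if (length(fs)) sort(fs[fs > th$reporting_floor], decreasing = TRUE) else fs

  structure(list(
    sample_id = v$sample_id,
    category = category,
    top_class = top_class,
    top_class_score = top_class_score,
    top_family = if (is.finite(top_family_score)) top_family else NA_character_,
    family_score = if (is.finite(top_family_score)) top_family_score else NA_real_,
    subclass = subclass,
    subclass_score = subclass_score,
    listed_scores = listed,
    listed_family_scores = listed_fam,
    control_score = control_sum,
    flags = flags,
    notes = notes,
    thresholds = th
  ), class = "decision_report")
}

#' Format a decision report as text
#'
#' Deterministic plain-text block: the category, the scores above the
#' reporting floor in descending order (class and family level), flags and
#' interpretation notes. Exactly the scores above the floor appear.
#'
#' @param report A [decide()] result.
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  stopifnot(inherits(report, "decision_report"))
  lines <- c(
    sprintf("sample: %s", report$sample_id),
    sprintf("category: %s", report$category),
    sprintf("top class: %s (calibrated score %.4f)", report$top_class,
            report$top_class_score)
  )
  if (!is.na(report$top_family)) {
    lines <- c(lines, sprintf("top family: %s (family score %.4f)",
                              report$top_family, report$family_score))
  }
  if (!is.na(report$subclass)) {
    lines <- c(lines, sprintf("subclass: %s (class score %.4f)",
                              report$subclass, report$subclass_score))
  }
  if (length(report$listed_scores) > 0) {
    lines <- c(lines, "scores above reporting floor:",
               sprintf("  %s: %.4f", names(report$listed_scores),
                       report$listed_scores))
  } else {
    lines <- c(lines, "scores above reporting floor: none")
  }
  if (length(report$listed_family_scores) > 0) {
    lines <- c(lines, "family scores above reporting floor:",
               sprintf("  %s: %.4f", names(report$listed_family_scores),
                       report$listed_family_scores))
  }
  if (length(report$flags) > 0) {
    lines <- c(lines, sprintf("flag: %s", report$flags))
  }
  if (length(report$notes) > 0) {
    lines <- c(lines, sprintf("note: %s", report$notes))
  }
  lines
}

#' @export
print.decision_report <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' Read a table of calibrated score vectors
#'
#' Wide TSV: one `sample_id` column, then one column per schema class.
#'
#' @param path TSV path.
#' @param schema A [class_schema()] to validate against.
#' @return Named list of [score_vector()].
#' @export
read_score_table <- function(path, schema) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(d)) stop("score table needs a sample_id column")
  out <- lapply(seq_len(nrow(d)), function(i) {
    s <- unlist(d[i, setdiff(names(d), "sample_id")])
    score_vector(s, schema, sample_id = d$sample_id[i])
  })
  names(out) <- d$sample_id
  out
}

#' Write a table of calibrated score vectors
#'
#' @param vectors List of [score_vector()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(vectors, path) {
  stopifnot(length(vectors) >= 1)
  cls <- names(vectors[[1]]$scores)
  d <- data.frame(sample_id = vapply(vectors, `[[`, "", "sample_id"),
                  stringsAsFactors = FALSE, check.names = FALSE)
  m <- t(vapply(vectors, function(v) v$scores[cls], numeric(length(cls))))
  colnames(m) <- cls
  d <- cbind(d, as.data.frame(m, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The worked glioblastoma score vector
#'
#' A reference fixture: an IDH-wild-type glioblastoma scoring
#' GBM, RTK I = 0.6; GBM, MES = 0.2; GBM, RTK II = 0.07; GBM, MID = 0.04;
#' GBM, RTK III = 0.01; GBM, MYCN = 0.01 — a family score of 0.93, above the
#' 0.9 threshold, with subclass RTK I (0.6 >= 0.5). The remaining probability
#' mass (0.07) is spread uniformly over all other classes.
#'
#' @param schema A [class_schema()] (default: bundled v11b4).
#' @return A [score_vector()].
#' @export
gbm_worked_example <- function(schema = read_class_schema()) {
  fixed <- c("GBM, RTK I" = 0.6, "GBM, MES" = 0.2, "GBM, RTK II" = 0.07,
             "GBM, MID" = 0.04, "GBM, RTK III" = 0.01, "GBM, MYCN" = 0.01)
  cls <- schema$classes$class
  if (!all(names(fixed) %in% cls)) {
    stop("schema lacks the glioblastoma family member classes")
  }
  rest <- setdiff(cls, names(fixed))
  s <- stats::setNames(rep((1 - sum(fixed)) / length(rest), length(rest)), rest)
  score_vector(c(fixed, s), schema, sample_id = "GBM_worked_example")
}
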