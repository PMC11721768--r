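#' Validate a long-format cohort table
#'
#' Checks the invariants of a cohort of scored motor-function tests: ages
#' positive, scores in [0, 100], (child_id, age_years) unique, and every
#' child's rows sharing one sex and one GMFCS level.  Row numbers are named in
#' every diagnostic.
#'
#' @param x a data.frame with columns \code{child_id}, \code{level},
#'   \code{age_years}, \code{score} (\code{sex} optional).
#' @return \code{x}, invisibly, with class \code{cohort}.
#' @export
validate_cohort <- function(x) {
  need <- c("child_id", "level", "age_years", "score")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing required columns: ", paste(miss, collapse = ", "))
  if (nrow(x) == 0) stop("cohort is empty")
  bad <- function(cond, what) {
    if (any(cond)) stop(what, " at row(s) ", paste(utils::head(which(cond), 5), collapse = ", "),
                        if (sum(cond) > 5) " ..." else "")
  }
  bad(!is.finite(x$age_years) | x$age_years <= 0, "age_years must be positive")
  bad(!is.finite(x$score) | x$score < 0 | x$score > 100, "score outside [0, 100]")
  level_index(x$level)  # errors on bad tokens
  bad(duplicated(x[, c("child_id", "age_years")]), "duplicate (child_id, age_years)")
  if ("sex" %in% names(x)) {
    nsex <- tapply(x$sex, x$child_id, function(s) length(unique(s)))
    if (any(nsex > 1)) stop("children with inconsistent sex: ",
                            paste(utils::head(names(nsex)[nsex > 1], 5), collapse = ", "))
  }
  nlev <- tapply(x$level, x$child_id, function(l) length(unique(l)))
  if (any(nlev > 1)) stop("children with inconsistent GMFCS level: ",
                          paste(utils::head(names(nlev)[nlev > 1], 5), collapse = ", "))
  if (!inherits(x, "cohort")) class(x) <- c("cohort", class(x))
  invisible(x)
}

#' Read and write cohort files
#'
#' Cohorts are exchanged as comma-separated text with a mandatory header and
#' columns \code{child_id,sex,level,age_years,score} (\code{sex} and
#' \code{subtype} optional).  GMFCS levels are accepted as I..V or 1..5 and
#' written as I..V.  Ages and scores are written with two decimals.
#'
#' @param path file path.
#' @param x a validated cohort data.frame.
#' @return \code{read_cohort} a \code{cohort} data.frame;
#'   \code{write_cohort} the path, invisibly.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("child_id", "level", "age_years", "score")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("'", path, "' lacks required column(s): ",
                         paste(miss, collapse = ", "))
  for (col in c("age_years", "score")) {
    v <- suppressWarnings(as.numeric(x[[col]]))
    if (anyNA(v) && !anyNA(x[[col]]))
      stop("unparseable numeric in '", col, "' at line ",
           which(is.na(v))[1] + 1L)  # +1 for the header line
    x[[col]] <- v
  }
  x$child_id <- as.character(x$child_id)
  x$level <- .gmfcs_levels[level_index(x$level)]
  validate_cohort(x)
  x
}

#' @rdname read_cohort
#' @export
write_cohort <- function(x, path) {
  validate_cohort(x)
  out <- as.data.frame(x)
  cols <- intersect(c("child_id", "sex", "level", "age_years", "score", "subtype"),
                    names(out))
  out <- out[, cols]
  out$age_years <- sprintf("%.2f", out$age_years)
  out$score <- sprintf("%.2f", out$score)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarize a cohort, one row per GMFCS level plus an overall row
#'
#' Reproduces the layout of a study-population characteristics table:
#' children per level, percent girls, age range, score range and mean
#' observations per child, with percentages rounded to integers and an
#' overall row.  When a \code{subtype} column is present, subtype counts and
#' percentages are attached as an attribute.
#'
#' @param cohort a validated cohort.
#' @return a data.frame of class \code{cohort_summary} with columns
#'   \code{level}, \code{n_children}, \code{pct_girls}, \code{age_min},
#'   \code{age_max}, \code{score_min}, \code{score_max},
#'   \code{mean_obs_per_child}, \code{n_obs}.
#' @export
summarize_cohort <- function(cohort) {
  validate_cohort(cohort)
  cohort$level <- .gmfcs_levels[level_index(cohort$level)]
  one <- function(d, lab) {
    kids <- !duplicated(d$child_id)
    nk <- sum(kids)
    pg <- if ("sex" %in% names(d))
      round(100 * sum(d$sex[kids] == "female") / nk) else NA_real_
    data.frame(level = lab, n_children = nk, pct_girls = pg,
               age_min = min(d$age_years), age_max = max(d$age_years),
               score_min = min(d$score), score_max = max(d$score),
               mean_obs_per_child = nrow(d) / nk, n_obs = nrow(d))
  }
  parts <- lapply(.gmfcs_levels, function(l) {
    d <- cohort[cohort$level == l, , drop = FALSE]
    if (nrow(d)) one(d, l) else NULL
  })
  out <- do.call(rbind, c(parts, list(one(cohort, "All"))))
  rownames(out) <- NULL
  out$pct_children <- round(100 * out$n_children / out$n_children[out$level == "All"])
  if ("subtype" %in% names(cohort)) {
    kids <- cohort[!duplicated(cohort$child_id), ]
    tab <- table(kids$subtype)
    attr(out, "subtypes") <- data.frame(
      subtype = names(tab), n = as.integer(tab),
      pct = round(100 * as.integer(tab) / sum(tab)))
  }
  class(out) <- c("cohort_summary", "data.frame")
  out
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary:", x$n_children[x$level == "All"], "children,",
      x$n_obs[x$level == "All"], "tests\n")
  disp <- data.frame(
    Level = x$level, N = x$n_children, `Girls (%)` = x$pct_girls,
    `Age range` = sprintf("%.1f to %.1f", x$age_min, x$age_max),
    Scores = sprintf("%g to %g", round(x$score_min), round(x$score_max)),
    `Mean obs` = sprintf("%.1f", x$mean_obs_per_child),
    check.names = FALSE)
  print(disp, row.names = FALSE)
  st <- attr(x, "subtypes")
  if (!is.null(st)) {
    cat("Subtypes:\n")
    print(st, row.names = FALSE)
  }
  invisible(x)
}

#' Reconstruct the published cohort margins as a synthetic fixture
#'
#' Builds a cohort whose summary table reproduces, exactly, the printed
#' study-population characteristics of the Norwegian registry cohort: 1206
#' children (631/198/108/128/141 at GMFCS I-V) with 3612 tests, 482 girls,
#' the per-level age ranges, score ranges and mean observations per child.
#' Only those margins are matched; the scores inside the ranges are
#' synthetic filler (linear interpolation between the printed extremes), so
#' the fixture supports descriptive arithmetic only, never curve fitting.
#'
#' @return a \code{cohort} data.frame.
#' @export
table1_fixture <- function() {
  n_kids <- c(631L, 198L, 108L, 128L, 141L)
  girls <- c(256L, 81L, 42L, 48L, 55L)          # sums to 482; rounds to 41/41/39/38/39
  n_obs <- c(1798L, 680L, 336L, 395L, 403L)     # sums to 3612; means round to 2.8/3.4/3.1/3.1/2.9
  age_lo <- c(0.7, 0.5, 0.9, 0.6, 0.7)
  age_hi <- c(17.3, 16.6, 17.0, 13.4, 15.8)
  sc_lo <- c(22, 23, 22, 4, 4)
  sc_hi <- c(100, 96, 73, 65, 45)
  rows <- vector("list", 5)
  for (g in 1:5) {
    nk <- n_kids[g]; no <- n_obs[g]
    # spread the extra observations over the first children
    per <- rep(no %/% nk, nk)
    per[seq_len(no %% nk)] <- per[seq_len(no %% nk)] + 1L
    cid <- rep(sprintf("L%d_%04d", g, seq_len(nk)), per)
    sex <- rep(c(rep("female", girls[g]), rep("male", nk - girls[g])), per)
    # ages unique within child: child j, test k gets a distinct offset
    age <- unlist(lapply(seq_len(nk), function(j) {
      k <- per[j]
      a <- age_lo[g] + (j - 1) / nk * (age_hi[g] - age_lo[g]) +
        (seq_len(k) - 1) * 0.01
      a[a > age_hi[g]] <- age_hi[g] - (seq_len(sum(a > age_hi[g]))) * 0.005
      round(a, 3)
    }))
    idx <- seq_len(no)
    score <- sc_lo[g] + (idx - 1) / max(no - 1, 1) * (sc_hi[g] - sc_lo[g])
    rows[[g]] <- data.frame(child_id = cid, sex = sex,
                            level = .gmfcs_levels[g],
                            age_years = age, score = round(score, 2))
  }
  out <- do.call(rbind, rows)
  # pin the printed extremes exactly despite rounding
  for (g in 1:5) {
    i <- which(out$level == .gmfcs_levels[g])
    out$age_years[i[which.min(out$age_years[i])]] <- age_lo[g]
    out$age_years[i[which.max(out$age_years[i])]] <- age_hi[g]
  }
  rownames(out) <- NULL
  validate_cohort(out)
  out
}
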