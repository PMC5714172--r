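#' Normalize raw band intensities into product fractions
#'
#' Converts per-lane densitometry intensities for the four product bands
#' into fractions summing to one.
#'
#' @param raw Numeric matrix or data frame of nonnegative intensities,
#'   one row per lane, columns `SC`, `N`, `L`, `EX` (a `BB` column is
#'   accepted as an alias for `EX`).
#' @return Matrix of per-lane fractions with rows summing to 1.
#' @examples
#' normalize_lanes(rbind(c(1, 1, 1, 1), c(3, 1, 0, 0)))
#' @export
normalize_lanes <- function(raw) {
  m <- as.matrix(raw)
  if (!is.null(colnames(m)) && "BB" %in% colnames(m) &&
      !"EX" %in% colnames(m)) {
    colnames(m)[colnames(m) == "BB"] <- "EX"
  }
  if (is.null(colnames(m))) colnames(m) <- c("SC", "N", "L", "EX")
  stopifnot(ncol(m) == 4L)
  if (any(m < 0)) stop("negative band intensity", call. = FALSE)
  tot <- rowSums(m)
  zero <- which(tot == 0)
  if (length(zero)) {
    stop("all-zero lane(s): ", paste(zero, collapse = ", "), call. = FALSE)
  }
  m / tot
}

#' Assemble a validated quantification table
#'
#' A quantification table holds product fractions per gel lane, indexed
#' either by mutant monomer fraction (`series = "mixing"`) or by time in
#' hours (`series = "timecourse"`). Row sums may deviate from 1 by at
#' most `tol` before normalization (densitometry slack) and are
#' renormalized to exactly 1.
#'
#' @param df Data frame with columns `lane`, `f` (mixing) or `time_h`
#'   (timecourse), and `SC`, `N`, `L`, `EX` (`BB` accepted for `EX`).
#' @param series `"mixing"` or `"timecourse"`.
#' @param scenario_label Optional free-text provenance label.
#' @param tol Allowed pre-normalization deviation of row sums from 1.
#' @return A data frame of class `quant_table`.
#' @export
quant_table <- function(df, series = c("mixing", "timecourse"),
                        scenario_label = NULL, tol = 0.02) {
  series <- match.arg(series)
  df <- as.data.frame(df)
  if ("BB" %in% names(df) && !"EX" %in% names(df)) {
    names(df)[names(df) == "BB"] <- "EX"
  }
  idx_col <- if (series == "mixing") "f" else "time_h"
  need <- c("lane", idx_col, "SC", "N", "L", "EX")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("quantification table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[, need]
  fr <- as.matrix(df[, c("SC", "N", "L", "EX")])
  if (any(fr < 0 | fr > 1)) {
    stop("fractions must lie in [0, 1]", call. = FALSE)
  }
  if (series == "mixing" && any(df$f < 0 | df$f > 1)) {
    stop("mutant fractions must lie in [0, 1]", call. = FALSE)
  }
  sums <- rowSums(fr)
  bad <- which(abs(sums - 1) > tol)
  if (length(bad)) {
    stop("lane(s) ", paste(df$lane[bad], collapse = ", "),
         ": fractions sum to ", paste(signif(sums[bad], 4), collapse = ", "),
         " (allowed deviation from 1 is ", tol, ")", call. = FALSE)
  }
  df[, c("SC", "N", "L", "EX")] <- fr / sums
  attr(df, "series") <- series
  attr(df, "scenario_label") <- scenario_label
  class(df) <- c("quant_table", "data.frame")
  df
}

#' Candidate set for model discrimination
#'
#' @param models Character vector of model names (default all six).
#' @param scenario A [mixing_scenario()] or mode string.
#' @param ordering Ordering-rule mode.
#' @return A list of candidate descriptors for [fit_mixing_data()].
#' @export
candidate_set <- function(models = cleavage_model_names(),
                          scenario = "equilibrated",
                          ordering = "strict_gate") {
  scenario <- .as_scenario(scenario)
  ordering <- .as_ordering(ordering)
  lapply(models, function(m) {
    list(model = .as_cleavage_model(m)$name, scenario = scenario,
         ordering = ordering$mode)
  })
}

#' Discriminate cleavage models against a mixing series
#'
#' Scores every candidate (model, scenario, ordering) against measured
#' or synthetic product fractions by unweighted least squares over all
#' four product classes and all lanes. The candidate curves contain no
#' free parameters — they are fully determined by the lane's mutant
#' fraction — so the residual sum of squares (RSS) compares the data to
#' parameter-free overlays. Candidates whose predictions are analytically
#' identical (agreeing within `1e-9` on a dense grid) are grouped into
#' equivalence classes before ranking, and candidates are excluded when
#' their RSS exceeds the best class's by more than `rejection_ratio`.
#'
#' @param data A [quant_table()] with `series = "mixing"`.
#' @param candidates List of candidates from [candidate_set()].
#' @param rejection_ratio Exclusion threshold on `RSS / best RSS`
#'   (default 2).
#' @return An object of class `fit_report`: a data frame with one row
#'   per candidate (`model`, `scenario`, `ordering`, `rss`, `class`,
#'   `rank`, `excluded`), best class first.
#' @examples
#' tab <- gen_mixing_dataset("mm_13_24", "equilibrated",
#'                           f_grid = seq(0, 1, by = 1 / 6),
#'                           noise = noise_spec(sd = 0, seed = 1))
#' fit_mixing_data(tab, candidate_set(scenario = "equilibrated"))
#' @export
fit_mixing_data <- function(data, candidates = candidate_set(),
                            rejection_ratio = 2) {
  stopifnot(inherits(data, "quant_table"))
  if (!identical(attr(data, "series"), "mixing")) {
    stop("fit_mixing_data needs a mixing series", call. = FALSE)
  }
  if (!length(candidates)) stop("no candidates supplied", call. = FALSE)
  obs <- as.matrix(data[, c("SC", "N", "L", "EX")])

  preds <- lapply(candidates, function(cand) {
    t(vapply(data$f, function(f)
      predict_endpoint(cand$model, cand$scenario, cand$ordering, f),
      numeric(4)))
  })
  rss <- vapply(preds, function(p) sum((obs - p)^2), numeric(1))

  # analytic equivalence classes on a canonical dense grid
  grid <- seq(0, 1, length.out = 41)
  sigs <- lapply(candidates, function(cand) {
    as.vector(t(vapply(grid, function(f)
      predict_endpoint(cand$model, cand$scenario, cand$ordering, f),
      numeric(4))))
  })
  cls <- integer(length(candidates))
  next_cls <- 0L
  for (i in seq_along(sigs)) {
    for (j in seq_len(i - 1L)) {
      if (max(abs(sigs[[i]] - sigs[[j]])) < 1e-9) {
        cls[i] <- cls[j]
        break
      }
    }
    if (cls[i] == 0L) {
      next_cls <- next_cls + 1L
      cls[i] <- next_cls
    }
  }

  class_rss <- tapply(rss, cls, min)
  best <- min(class_rss)
  ranks <- rank(class_rss, ties.method = "min")
  out <- data.frame(
    model = vapply(candidates, `[[`, character(1), "model"),
    scenario = vapply(candidates, function(c_) .as_scenario(c_$scenario)$mode,
                      character(1)),
    ordering = vapply(candidates, `[[`, character(1), "ordering"),
    rss = rss,
    class = cls,
    rank = ranks[as.character(cls)],
    excluded = rss > rejection_ratio * best + 1e-12,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$rss, out$model), ]
  rownames(out) <- NULL
  attr(out, "rejection_ratio") <- rejection_ratio
  attr(out, "best_rss") <- best
  class(out) <- c("fit_report", "data.frame")
  out
}

#' @export
print.fit_report <- function(x, ...) {
  cat("<fit_report> parameter-free least squares, rejection ratio ",
      attr(x, "rejection_ratio"), "x\n", sep = "")
  print.data.frame(x, digits = 4)
  exc <- x$model[x$excluded]
  if (length(exc)) {
    cat("excluded:", paste(unique(exc), collapse = ", "), "\n")
  } else {
    cat("no candidate excluded\n")
  }
  invisible(x)
}
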