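# Published per-subject summary values of the reference study, shipped as
# plain-text fixtures so the group statistics can be recomputed.

#' Round half away from zero
#'
#' Printed tables round 0.5 up, unlike R's banker's rounding.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return Rounded numeric.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "mitrainr")
  if (p == "") stop("packaged fixture not found: ", name)
  p
}

#' Per-subject class-distance fixture
#'
#' Ten subjects' calibration class-distance values under the non-feedback
#' and trial-feedback paradigms (subjects S1--S5 trained, S6--S10
#' untrained).
#'
#' @return A data.frame with columns `subject`, `group`, `session`, `cd`.
#' @export
cd_table <- function() {
  utils::read.csv(fixture_path("table_cd.csv"), stringsAsFactors = FALSE)
}

#' Per-subject questionnaire-score fixture
#'
#' Ten subjects' mean questionnaire (Qn) scores (1--5 Likert, lower is
#' better) for the calibration and testing processes of both sessions.
#'
#' @return A data.frame with columns `subject`, `group`, `process`,
#'   `session`, `qn`.
#' @export
qn_table <- function() {
  utils::read.csv(fixture_path("table_qn.csv"), stringsAsFactors = FALSE)
}

#' Testing-run summary fixtures
#'
#' Run-level on-line accuracy summaries of the testing phase. The first
#' two testing runs use the 3-run decoder, the last two the 6-run
#' decoder; `slot` is the run's position within its stage (run-level
#' attribution within a stage follows figure reading order, only stage
#' aggregates are reproduced). `benchmark_table()` gives, per session and
#' stage, how many of the 2 runs x 10 subjects reached the 70%
#' BCI-literacy benchmark.
#'
#' @return `testing_run_table()`: data.frame with `session`, `stage`,
#'   `slot`, `mean_ca_pct`; `benchmark_table()`: data.frame with
#'   `session`, `stage`, `n_benchmark`.
#' @export
testing_run_table <- function() {
  utils::read.csv(fixture_path("testing_runs.csv"), stringsAsFactors = FALSE)
}

#' @rdname testing_run_table
#' @export
benchmark_table <- function() {
  utils::read.csv(fixture_path("benchmark_counts.csv"),
                  stringsAsFactors = FALSE)
}

#' Recompute the published group statistics from the fixtures
#'
#' From the per-subject fixture values: group and all-subject means of
#' class distance and questionnaire scores, the paired t-tests between
#' sessions, the fraction of testing runs reaching the 70% benchmark, and
#' the stage-average on-line accuracies. Means are rounded to 2 decimals
#' and p-values to 4, half up, matching the printed precision.
#'
#' @return A list of class `stat_report`: `cd_means` (by group and
#'   session), `cd_p`, `qn_means`, `qn_cal_p`, `qn_test_p`,
#'   `benchmark_pct`, `stage_means` (percent, first/last two testing
#'   runs).
#' @export
reproduce_tables <- function() {
  cd <- cd_table()
  qn <- qn_table()
  tr <- testing_run_table()
  bm <- benchmark_table()

  grp_means <- function(df, value) {
    agg <- function(sub) round_half_up(mean(sub[[value]]), 2)
    out <- list()
    for (s in unique(df$session)) {
      d <- df[df$session == s, ]
      out[[s]] <- c(trained = agg(d[d$group == "trained", ]),
                    untrained = agg(d[d$group == "untrained", ]),
                    all = agg(d))
    }
    out
  }

  wide <- function(df, value) {
    # subject-order-aligned session vectors for pairing
    sess <- unique(df$session)
    sapply(sess, function(s) {
      d <- df[df$session == s, ]
      d[[value]][order(d$subject)]
    })
  }

  cdw <- wide(cd, "cd")
  qcal <- wide(qn[qn$process == "calibration", ], "qn")
  qtest <- wide(qn[qn$process == "testing", ], "qn")

  p4 <- function(m) round_half_up(
    paired_ttest(m[, "non_feedback"], m[, "trial_feedback"])$p, 4)

  n_run_cells <- nrow(tr) * 10  # 10 subjects per session-run cell
  stage_mean <- function(stage)
    round_half_up(mean(tr$mean_ca_pct[tr$stage == stage]), 0)

  structure(list(
    cd_means = grp_means(cd, "cd"),
    cd_p = p4(cdw),
    qn_means = list(calibration = grp_means(qn[qn$process == "calibration", ], "qn"),
                    testing = grp_means(qn[qn$process == "testing", ], "qn")),
    qn_cal_p = p4(qcal),
    qn_test_p = p4(qtest),
    benchmark_pct = round_half_up(100 * sum(bm$n_benchmark) / n_run_cells, 2),
    stage_means = c(first_two = stage_mean("first_two"),
                    last_two = stage_mean("last_two"))
  ), class = "stat_report")
}
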