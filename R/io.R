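# Long-format CSV interchange: one row per (subject, visit), with the
# subject-level follow-up record repeated on every row and checked for
# consistency on read.

#' Write a dataset to long-format CSV
#'
#' Columns: `id`, `visit` (0-based), `visit_time`, `exposure`, the
#' confounder columns `L1..Lp`, and the subject-level fields
#' `followup_time`, `event`, `admin_end` (identical on every row of a
#' subject). Values round-trip through [read_long_csv()] at full double
#' precision (15 significant digits).
#'
#' @param data An `sncstm_data` object.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_long_csv <- function(data, path) {
  d <- as_sncstm_data(data)
  K <- d$K
  p <- d$p
  rows <- vector("list", K + 1L)
  for (k in 0:K) {
    Lk <- matrix(d$L[, , k + 1L], nrow = d$n)
    colnames(Lk) <- paste0("L", seq_len(p))
    rows[[k + 1L]] <- data.frame(
      id = d$id, visit = k, visit_time = d$S[, k + 1L],
      exposure = d$A[, k + 1L], Lk,
      followup_time = d$time, event = d$event, admin_end = d$admin_end,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$id, d$id), out$visit), ]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format CSV dataset
#'
#' Parses and validates the format written by [write_long_csv()]: required
#' columns present, visit indices contiguous from 0, no duplicated
#' (id, visit) pairs, and subject-level fields constant within subject.
#' The assembled dataset is passed through [validate_dataset()] via
#' [as_sncstm_data()], so the returned object is ready for estimation.
#'
#' @param path CSV file path.
#' @param confounder_prefix Prefix of the confounder columns (default
#'   `"L"`; columns are `L1`, `L2`, ...).
#' @return An `sncstm_data` object.
#' @export
read_long_csv <- function(path, confounder_prefix = "L") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "visit", "visit_time", "exposure",
            "followup_time", "event", "admin_end")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lcols <- grep(paste0("^", confounder_prefix, "[0-9]+$"), names(df),
                value = TRUE)
  if (length(lcols) == 0L) {
    stop("no confounder columns found (expected ", confounder_prefix,
         "1, ...)", call. = FALSE)
  }
  lcols <- lcols[order(as.integer(sub(confounder_prefix, "", lcols)))]
  df$id <- as.character(df$id)
  dup <- duplicated(df[, c("id", "visit")])
  if (any(dup)) {
    stop("duplicated (id, visit) pair for id ", df$id[which(dup)[1]],
         " at row ", which(dup)[1], call. = FALSE)
  }
  subjects <- list()
  for (id in unique(df$id)) {
    rows <- df[df$id == id, ]
    rows <- rows[order(rows$visit), ]
    K <- nrow(rows) - 1L
    if (!identical(as.integer(rows$visit), 0:K)) {
      stop("visits for id ", id, " are not contiguous from 0", call. = FALSE)
    }
    for (col in c("followup_time", "event", "admin_end")) {
      if (length(unique(rows[[col]])) != 1L) {
        stop("subject-level column '", col, "' varies within id ", id,
             call. = FALSE)
      }
    }
    subjects[[length(subjects) + 1L]] <- subject_history(
      id = id,
      visit_times = rows$visit_time,
      exposures = rows$exposure,
      confounders = as.matrix(rows[, lcols, drop = FALSE]),
      followup_time = rows$followup_time[1],
      event = rows$event[1],
      admin_end = rows$admin_end[1]
    )
  }
  as_sncstm_data(subjects)
}

long_to_data <- function(df, confounder_prefix = "L") {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  read_long_csv(tmp, confounder_prefix = confounder_prefix)
}
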