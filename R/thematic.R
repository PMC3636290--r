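#' Read a coded dialogue-act table
#'
#' Thematic analysis input: human-coded dialogue acts (one communicative
#' function per utterance fragment) as a CSV with columns
#' `meeting_id,coder_id,act_index,theme`. Each (meeting, coder, act_index)
#' must be unique.
#'
#' @param path path to the CSV file.
#' @param scheme optional character vector of allowed theme codes; when
#'   given, unknown themes are a validation error.
#' @return Data frame of coded acts.
#' @export
read_coded_acts <- function(path, scheme = NULL) {
  if (!file.exists(path)) {
    cs_error(sprintf("coded-acts file not found: %s", path),
             "consensim_format_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(meeting_id = "character",
                                       coder_id = "character",
                                       act_index = "integer",
                                       theme = "character"))
  required <- c("meeting_id", "coder_id", "act_index", "theme")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    cs_error(paste("coded-acts table missing column(s):",
                   paste(missing_cols, collapse = ", ")),
             "consensim_format_error")
  }
  if (any(is.na(df$act_index)) || any(df$act_index < 1L)) {
    cs_error("act_index must be an integer >= 1", "consensim_validation_error")
  }
  key <- paste(df$meeting_id, df$coder_id, df$act_index)
  if (anyDuplicated(key)) {
    cs_error(sprintf("duplicate (meeting, coder, act_index): %s",
                     key[duplicated(key)][1L]),
             "consensim_validation_error")
  }
  if (!is.null(scheme)) {
    bad <- which(!(df$theme %in% scheme))
    if (length(bad)) {
      cs_error(sprintf("theme outside the coding scheme at row(s): %s",
                       paste(utils::head(bad, 10L), collapse = ", ")),
               "consensim_validation_error")
    }
  }
  df
}

#' Integer percentage, half-up
#'
#' The printed-style percentage used throughout the report tables:
#' `round(100 * count / total)` with halves rounded up, e.g. 177 of 369
#' acts is 48%.
#'
#' @param count non-negative integer count, `<= total`.
#' @param total positive integer total.
#' @return Integer percent.
#' @export
theme_percentage <- function(count, total) {
  if (!is_scalar_number(total) || total < 1) {
    cs_error("total must be >= 1", "consensim_validation_error")
  }
  if (any(count < 0) || any(count > total)) {
    cs_error("count must be in [0, total]", "consensim_validation_error")
  }
  round_half_up(100 * count / total)
}

#' Tally coded dialogue acts by theme
#'
#' Counts acts per theme over a declared coding scheme (unused codes count
#' zero) with half-up integer percentages of the total.
#'
#' @param acts coded-act table (see [read_coded_acts()]); only the `theme`
#'   column is used.
#' @param scheme ordered character vector of theme codes.
#' @return Data frame with columns `theme`, `count`, `percent`, in scheme
#'   order; the act total is stored in the `total` attribute.
#' @export
tally_themes <- function(acts, scheme) {
  themes <- if (is.data.frame(acts)) acts$theme else acts
  if (!length(themes)) cs_error("empty tally", "consensim_validation_error")
  bad <- setdiff(unique(themes), scheme)
  if (length(bad)) {
    cs_error(sprintf("theme(s) outside the coding scheme: %s",
                     paste(bad, collapse = ", ")),
             "consensim_validation_error")
  }
  counts <- table(factor(themes, levels = scheme))
  total <- length(themes)
  out <- data.frame(theme = scheme, count = as.integer(counts),
                    percent = theme_percentage(as.integer(counts), total),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- total
  out
}

#' Cohen's kappa between two coders
#'
#' Inter-analyst agreement on aligned act labels:
#' `kappa = (Po - Pe) / (1 - Pe)` with `Po` the fraction of identically
#' coded acts and `Pe` the product-marginal chance agreement
#' `sum_c p_a(c) * p_b(c)`. Two coders who agree on every act get 1 (also
#' when both are constant, where the chance term degenerates).
#'
#' @param labels_a,labels_b equal-length label vectors aligned by act.
#' @return Cohen's kappa.
#' @export
intercoder_kappa <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b) || !length(labels_a)) {
    cs_error("label vectors must be aligned and non-empty",
             "consensim_validation_error")
  }
  n <- length(labels_a)
  po <- mean(labels_a == labels_b)
  levs <- union(labels_a, labels_b)
  pa <- table(factor(labels_a, levels = levs)) / n
  pb <- table(factor(labels_b, levels = levs)) / n
  pe <- sum(pa * pb)
  if (pe == 1) return(if (po == 1) 1 else NaN)
  (po - pe) / (1 - pe)
}

#' Discussion time between two timestamps
#'
#' @param start,end timestamps: `POSIXct`, or `"HH:MM:SS"` strings
#'   (interpreted on a common day).
#' @return Elapsed seconds (`end - start`), non-negative.
#' @export
discussion_time <- function(start, end) {
  to_time <- function(x) {
    if (inherits(x, "POSIXct")) return(as.numeric(x))
    if (is.character(x)) {
      parts <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1L]])
      if (length(parts) != 3L || anyNA(parts)) {
        cs_error(sprintf("cannot parse time '%s' (need HH:MM:SS)", x),
                 "consensim_format_error")
      }
      return(parts[1L] * 3600 + parts[2L] * 60 + parts[3L])
    }
    if (is.numeric(x)) return(x)
    cs_error("unsupported timestamp type", "consensim_format_error")
  }
  s <- to_time(start); e <- to_time(end)
  if (e < s) cs_error("end before start", "consensim_validation_error")
  e - s
}

#' Summarize discussion durations
#'
#' @param durations numeric vector of durations in seconds.
#' @return Named vector `c(mean, sd)` (sample SD).
#' @export
summarize_times <- function(durations) {
  if (!length(durations)) {
    cs_error("no durations to summarize", "consensim_validation_error")
  }
  c(mean = mean(durations), sd = stats::sd(durations))
}
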