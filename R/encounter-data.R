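#' Augmented encounter dataset for one study plot
#'
#' Container for everything the integrated model observes on one plot: the
#' capture / age-classification / resight histories of individual females,
#' the yearly counts of unmarked females, and the data-augmentation settings.
#' Rows of the matrices are individuals (observed individuals first, then
#' all-zero pseudo-individuals up to the augmentation bound `M`), columns are
#' study years.
#'
#' The marked indicator is derived data: a female is marked from her first
#' capture year onward.  Resightings can only occur while marked.
#'
#' @param capture Integer matrix (`M x T`) of capture indicators.
#' @param age_class Integer matrix (`M x T`): 0 = not captured, 1 = SY,
#'   2 = ASY, 3 = AHY (captured but age ambiguous).
#' @param resight Integer matrix (`M x T`) of resight indicators.
#' @param u Integer vector (length `T`) of yearly counts of unmarked females.
#' @param years Calendar years (length `T`).
#' @param area Plot area in hectares.
#' @param M Augmentation bound (if larger than `nrow(capture)`, all-zero
#'   rows are appended).
#' @param single_day Logical vector (length `T`): years in which the plot was
#'   surveyed on a single day, so resightings and counts carry the extra
#'   detection probability.
#' @param plot_id Plot identifier.
#' @return An object of class `encounter_data`.
#' @export
encounter_data <- function(capture, age_class, resight, u, years, area,
                           M = nrow(capture), single_day = NULL,
                           plot_id = "plot") {
  capture <- as.matrix(capture); storage.mode(capture) <- "integer"
  age_class <- as.matrix(age_class); storage.mode(age_class) <- "integer"
  resight <- as.matrix(resight); storage.mode(resight) <- "integer"
  T <- length(years)
  stopifnot(ncol(capture) == T, ncol(age_class) == T, ncol(resight) == T,
            nrow(age_class) == nrow(capture), nrow(resight) == nrow(capture),
            length(u) == T, area > 0, M >= nrow(capture))
  if (is.null(single_day)) single_day <- rep(FALSE, T)
  stopifnot(length(single_day) == T)
  if (M > nrow(capture)) {
    pad <- matrix(0L, M - nrow(capture), T)
    capture <- rbind(capture, pad)
    age_class <- rbind(age_class, pad)
    resight <- rbind(resight, pad)
  }
  marked <- t(apply(capture, 1L, cummax))
  if (T == 1) marked <- matrix(as.integer(capture), M, 1L)
  storage.mode(marked) <- "integer"
  obj <- structure(list(plot_id = plot_id, years = as.integer(years),
                        capture = capture, age_class = age_class,
                        marked = marked, resight = resight,
                        u = as.integer(u), single_day = as.logical(single_day),
                        M = as.integer(M), area = as.numeric(area)),
                   class = "encounter_data")
  validate_encounter_data(obj)
  obj
}

validate_encounter_data <- function(x) {
  if (any(x$resight == 1L & x$marked == 0L))
    stop("resightings recorded for unmarked individuals")
  if (any(x$capture == 1L & x$age_class == 0L))
    stop("captures must carry an age classification (SY/ASY/AHY)")
  if (any(x$capture == 0L & x$age_class != 0L))
    stop("age classifications recorded without capture")
  if (any(rowSums(x$capture) > 1L))
    stop("individuals can be captured (and aged) at most once")
  if (any(x$u < 0L)) stop("unmarked counts must be non-negative")
  invisible(x)
}

#' @export
print.encounter_data <- function(x, ...) {
  n_obs <- sum(rowSums(x$capture) > 0)
  cat("Integrated encounter dataset: plot", x$plot_id, "\n")
  cat("  years:", min(x$years), "-", max(x$years),
      sprintf("(T = %d)", length(x$years)), "\n")
  cat("  marked females:", n_obs, "  augmented to M =", x$M, "\n")
  cat("  unmarked counts:", paste(x$u, collapse = " "), "\n")
  cat("  area:", x$area, "ha;  single-day years:",
      if (any(x$single_day)) paste(x$years[x$single_day], collapse = " ")
      else "none", "\n")
  invisible(x)
}

#' Read an encounter dataset from delimited text
#'
#' Expects the long encounter format
#' `individual_id,year,captured,age_class,resighted` (age class `SY`, `ASY`,
#' `AHY`, or `NA` when not captured) together with a counts file
#' `year,unmarked_count`.
#'
#' @param encounter_file,counts_file Paths to the CSV files.
#' @param area Plot area (ha).
#' @param M Augmentation bound.
#' @param years Study years; defaults to the full range present in either
#'   file.
#' @param single_day_years Calendar years surveyed on a single day.
#' @param plot_id Plot identifier.
#' @return An [encounter_data()] object.
#' @export
read_encounters <- function(encounter_file, counts_file, area, M = 600,
                            years = NULL, single_day_years = integer(),
                            plot_id = "plot") {
  for (f in c(encounter_file, counts_file)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  enc <- read.csv(encounter_file, stringsAsFactors = FALSE)
  cnt <- read.csv(counts_file, stringsAsFactors = FALSE)
  need <- c("individual_id", "year", "captured", "age_class", "resighted")
  if (!all(need %in% names(enc)))
    stop("encounter file must have columns: ", paste(need, collapse = ", "))
  if (!all(c("year", "unmarked_count") %in% names(cnt)))
    stop("counts file must have columns: year, unmarked_count")
  if (is.null(years))
    years <- seq(min(c(enc$year, cnt$year)), max(c(enc$year, cnt$year)))
  T <- length(years)
  ids <- unique(enc$individual_id)
  n <- length(ids)
  capture <- age_class <- resight <- matrix(0L, n, T)
  code <- c(SY = 1L, ASY = 2L, AHY = 3L)
  for (r in seq_len(nrow(enc))) {
    i <- match(enc$individual_id[r], ids)
    t <- match(enc$year[r], years)
    if (is.na(t)) next
    capture[i, t] <- as.integer(enc$captured[r])
    resight[i, t] <- as.integer(enc$resighted[r])
    ac <- enc$age_class[r]
    if (capture[i, t] == 1L) {
      if (is.na(ac) || !ac %in% names(code))
        stop("captured individual without a valid age class at row ", r)
      age_class[i, t] <- code[[ac]]
    }
  }
  u <- integer(T)
  idx <- match(cnt$year, years)
  u[idx[!is.na(idx)]] <- as.integer(cnt$unmarked_count[!is.na(idx)])
  encounter_data(capture, age_class, resight, u, years, area, M = M,
                 single_day = years %in% single_day_years, plot_id = plot_id)
}

#' Write an encounter dataset to delimited text
#'
#' Writes the long-format encounter CSV and the counts CSV read back by
#' [read_encounters()].  Only observed (ever-captured) individuals are
#' written; augmentation rows are reconstructed at read time.
#'
#' @param data An [encounter_data()] object.
#' @param encounter_file,counts_file Output paths.
#' @return Invisibly, the two paths.
#' @export
write_encounters <- function(data, encounter_file, counts_file) {
  obs <- which(rowSums(data$capture) > 0)
  lab <- c("SY", "ASY", "AHY")
  rows <- list()
  for (i in obs) {
    first <- match(1L, data$marked[i, ])
    ts <- seq(first, length(data$years))
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = sprintf("f%04d", i),
      year = data$years[ts],
      captured = data$capture[i, ts],
      age_class = ifelse(data$age_class[i, ts] > 0L,
                         lab[pmax(data$age_class[i, ts], 1L)], NA),
      resighted = data$resight[i, ts])
  }
  enc <- if (length(rows)) do.call(rbind, rows)
         else data.frame(individual_id = character(), year = integer(),
                         captured = integer(), age_class = character(),
                         resighted = integer())
  write.csv(enc, encounter_file, row.names = FALSE)
  write.csv(data.frame(year = data$years, unmarked_count = data$u),
            counts_file, row.names = FALSE)
  invisible(c(encounter_file, counts_file))
}
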