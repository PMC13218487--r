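#' Partitioning scheme for a cognate matrix
#'
#' @slot scheme `"per_meaning"` (one partition per meaning), `"binned"`
#'   (meanings grouped by their cognate-set count into bins 1..binWidth,
#'   binWidth+1..2*binWidth, ...), or `"single"`.
#' @slot binWidth Cognate-count bin width for the binned scheme.
#' @slot weightsMode `"cognates"` (weight = observed cognate columns),
#'   `"meanings"` (weight = meanings per partition) or `"equal"`.
#' @export
setClass("PartitionSpec",
  representation(scheme = "character", binWidth = "numeric", weightsMode = "character"))

#' Construct a partition specification
#' @param scheme,binWidth,weightsMode See [PartitionSpec-class].
#' @export
partitionSpec <- function(scheme = c("per_meaning", "binned", "single"),
                          binWidth = 5,
                          weightsMode = c("cognates", "meanings", "equal")) {
  new("PartitionSpec", scheme = match.arg(scheme), binWidth = binWidth,
      weightsMode = match.arg(weightsMode))
}

parseValue <- function(x) {
  v <- suppressWarnings(as.integer(x))
  v[x %in% c("?", "-")] <- NA_integer_
  if (any(is.na(v) & !(x %in% c("?", "-"))) || any(!v %in% c(0L, 1L, NA)))
    stop("non-binary symbol in cognate data: ",
         paste(unique(x[!x %in% c("0", "1", "?", "-")]), collapse = ", "))
  v
}

#' Read a partitioned cognate matrix
#'
#' Two dialects are supported. `csv`: long format with columns
#' `language, meaning, cognate_id, value` where value is 0, 1 or `?`
#' (missing). `nexus`: a standard DATA block with `SYMBOLS="01"` plus a SETS
#' block whose CHARSET lines name the meanings.
#'
#' @param path File path.
#' @param format `"csv"` or `"nexus"` (default guessed from the extension).
#' @return A [CognateMatrix-class] object (ascertainment status unknown,
#'   flagged raw).
#' @export
readCognateMatrix <- function(path, format = c("auto", "csv", "nexus")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.nex(us)?$", path, ignore.case = TRUE)) "nexus" else "csv"
  if (format == "csv") readCognateCsv(path) else readCognateNexus(path)
}

readCognateCsv <- function(path) {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("language", "meaning", "cognate_id", "value")
  if (!all(need %in% names(df)))
    stop("csv must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0 || !length(unique(df$meaning)))
    stop("empty meaning list")
  langs <- unique(df$language)
  cogs <- unique(df$cognate_id)
  meaningOf <- df$meaning[match(cogs, df$cognate_id)]
  bad <- tapply(df$meaning, df$cognate_id, function(m) length(unique(m)) > 1)
  if (any(bad)) stop("cognate set assigned to more than one meaning: ",
                     paste(names(bad)[bad], collapse = ", "))
  v <- matrix(NA_integer_, length(langs), length(cogs),
              dimnames = list(langs, cogs))
  v[cbind(match(df$language, langs), match(df$cognate_id, cogs))] <- parseValue(df$value)
  cognateMatrix(v, meaningOf, ascertained = FALSE)
}

readCognateNexus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  txt <- paste(lines, collapse = "\n")
  mat <- regmatches(txt, regexpr("MATRIX[^;]*;", txt, ignore.case = TRUE))
  if (!length(mat)) stop("no MATRIX block found")
  rows <- strsplit(mat, "\n")[[1]][-1]
  rows <- trimws(sub(";", "", rows))
  rows <- rows[nzchar(rows)]
  taxa <- sub("\\s.*$", "", rows)
  seqs <- gsub("\\s", "", sub("^\\S+\\s+", "", rows))
  if (anyDuplicated(taxa)) stop("duplicate language names in NEXUS matrix")
  v <- t(vapply(seqs, function(s) parseValue(strsplit(s, "")[[1]]),
                integer(nchar(seqs[1]))))
  rownames(v) <- taxa
  csets <- regmatches(txt, gregexpr("(?i)CHARSET[^;]*;", txt, perl = TRUE))[[1]]
  if (!length(csets)) stop("no CHARSET lines: every column needs a meaning")
  meaning <- rep(NA_character_, ncol(v))
  for (cs in csets) {
    body <- sub(";", "", sub("(?i)^\\s*CHARSET\\s+", "", cs, perl = TRUE))
    parts <- strsplit(body, "=")[[1]]
    nm <- trimws(parts[1])
    idx <- integer(0)
    for (tok in strsplit(trimws(parts[2]), "[[:space:],]+")[[1]]) {
      if (grepl("-", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1]])
        idx <- c(idx, seq(ab[1], ab[2]))
      } else idx <- c(idx, as.integer(tok))
    }
    meaning[idx] <- nm
  }
  if (any(is.na(meaning))) stop("column without meaning assignment")
  colnames(v) <- make.unique(paste(meaning, seq_len(ncol(v)), sep = "_"))
  cognateMatrix(v, meaning, ascertained = FALSE)
}

#' Write a cognate matrix
#'
#' @param m A [CognateMatrix-class] object.
#' @param path Output file.
#' @param format `"csv"` (long format) or `"nexus"` (DATA + SETS blocks).
#' @export
writeCognateMatrix <- function(m, path, format = c("csv", "nexus")) {
  format <- match.arg(format)
  v <- m@values
  if (format == "csv") {
    df <- data.frame(
      language = rep(rownames(v), times = ncol(v)),
      meaning = rep(m@partition, each = nrow(v)),
      cognate_id = rep(colnames(v), each = nrow(v)),
      value = as.vector(ifelse(is.na(v), "?", as.character(v))))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    chr <- ifelse(is.na(v), "?", as.character(v))
    rows <- paste(format(rownames(v)), apply(chr, 1, paste, collapse = ""))
    meanings <- unique(m@partition)
    csets <- vapply(meanings, function(mm) {
      idx <- which(m@partition == mm)
      sprintf("CHARSET %s = %s;", mm, paste(idx, collapse = " "))
    }, "")
    writeLines(c("#NEXUS", "BEGIN DATA;",
                 sprintf("DIMENSIONS NTAX=%d NCHAR=%d;", nrow(v), ncol(v)),
                 "FORMAT DATATYPE=STANDARD SYMBOLS=\"01\" MISSING=?;",
                 "MATRIX", rows, ";", "END;",
                 "BEGIN SETS;", csets, "END;"), path)
  }
  invisible(path)
}

#' Remove all-absent columns (ascertainment filter)
#'
#' Real cognate data cannot contain a cognate set absent from every language;
#' this filter applies the same censoring to simulated matrices.
#'
#' @param m A raw [CognateMatrix-class] object.
#' @param onEmpty What to do when a meaning loses all its columns:
#'   `"error"` (default; signals a degenerate simulation) or `"drop"`.
#' @return List with `matrix` (the ascertained [CognateMatrix-class]) and
#'   `removed` (named integer vector of removed columns per meaning).
#' @export
applyAscertainmentFilter <- function(m, onEmpty = c("error", "drop")) {
  onEmpty <- match.arg(onEmpty)
  stopifnot(is(m, "CognateMatrix"))
  v <- m@values
  keep <- colSums(v == 1L, na.rm = TRUE) > 0
  meanings <- unique(m@partition)
  removed <- vapply(meanings, function(mm) sum(!keep & m@partition == mm), 0L)
  emptied <- vapply(meanings, function(mm) !any(keep & m@partition == mm), TRUE)
  if (any(emptied) && onEmpty == "error")
    stop("meaning(s) left with zero columns after filtering: ",
         paste(meanings[emptied], collapse = ", "))
  out <- cognateMatrix(v[, keep, drop = FALSE], m@partition[keep],
                       ascertained = TRUE)
  list(matrix = out, removed = removed)
}

#' Build data partitions with weights
#'
#' @param m A [CognateMatrix-class] object.
#' @param spec A [PartitionSpec-class] object.
#' @return A list of partitions, each with elements `name`, `columns`
#'   (column indices into `m`), `meanings`, and `weight` per the spec's
#'   weights mode.
#' @export
buildPartitions <- function(m, spec = partitionSpec()) {
  stopifnot(is(m, "CognateMatrix"), is(spec, "PartitionSpec"))
  meanings <- unique(m@partition)
  counts <- vapply(meanings, function(mm) sum(m@partition == mm), 0L)
  groups <- switch(spec@scheme,
    per_meaning = lapply(meanings, function(mm) mm),
    single = list(meanings),
    binned = {
      bin <- (counts - 1) %/% spec@binWidth
      lapply(sort(unique(bin)), function(b) sort(meanings[bin == b]))
    },
    stop("unknown scheme: ", spec@scheme))
  names(groups) <- switch(spec@scheme,
    per_meaning = meanings,
    single = "all",
    binned = vapply(groups, function(g) {
      k <- counts[match(g[1], meanings)]
      b <- (k - 1) %/% spec@binWidth
      sprintf("bin_%d-%d", b * spec@binWidth + 1, (b + 1) * spec@binWidth)
    }, ""))
  lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    cols <- unlist(lapply(g, function(mm) which(m@partition == mm)), use.names = FALSE)
    w <- switch(spec@weightsMode,
      cognates = length(cols),
      meanings = length(g),
      equal = 1)
    list(name = names(groups)[i], columns = cols, meanings = g, weight = w)
  })
}
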