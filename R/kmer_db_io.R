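# On-disk database formats.
#
# Binary dialect ("MFKD"): magic "MFKD", version byte (1), k (1 byte),
# level byte (0=sample, 1=class, 2=sample_level, 3=class_level, 4=host,
# 255=unset), flags byte (bit0: counts present, bit1: host-subtracted),
# ci byte (255=unset), label length byte + label bytes, record count
# (8 bytes little-endian), then the sorted canonical k-mers 2-bit packed
# (A=0 C=1 G=2 T=3, first base in the two most significant bits,
# ceil(k/4) bytes each), followed by 32-bit little-endian counts when the
# counts flag is set.
#
# Text dialect: header line "#k=<k>\tlevel=<level>" (plus label / counted /
# ci / host_subtracted fields), then one "KMER\tCOUNT" (or bare "KMER")
# line per record, sorted.

.level_codes <- c(sample = 0L, class = 1L, sample_level = 2L,
                  class_level = 3L, host = 4L)

level_to_code <- function(level) {
  if (is.na(level)) return(255L)
  code <- .level_codes[[level]]
  if (is.null(code)) stop_format(sprintf("unknown level '%s'", level))
  code
}

code_to_level <- function(code) {
  if (code == 255L) return(NA_character_)
  lv <- names(.level_codes)[match(code, .level_codes)]
  if (is.na(lv)) stop_format(sprintf("unknown level code %d", code))
  lv
}

db_fields <- function(db) {
  if (inherits(db, "kmer_counted_db")) {
    list(counted = TRUE, level = db$level, ci = NA_integer_,
         host_subtracted = FALSE)
  } else {
    p <- db$provenance
    list(counted = FALSE, level = p$level, ci = p$ci,
         host_subtracted = isTRUE(p$host_subtracted))
  }
}

#' Write a k-mer database to disk
#'
#' Both the compact sorted 2-bit-packed binary dialect and a
#' human-readable TSV dialect are supported; [load_kmer_db()] restores an
#' identical object from either (`load(save(db)) == db`).
#'
#' @param db A `kmer_counted_db` or `kmer_set`.
#' @param path Output file path.
#' @param format `"binary"` or `"text"`.
#' @return `path`, invisibly.
#' @export
save_kmer_db <- function(db, path, format = c("binary", "text")) {
  format <- match.arg(format)
  stopifnot(inherits(db, "kmer_counted_db") || inherits(db, "kmer_set"))
  f <- db_fields(db)
  if (format == "text") {
    header <- sprintf(
      "#k=%d\tlevel=%s\tlabel=%s\tcounted=%d\tci=%s\thost_subtracted=%d",
      db$k, as.character(f$level), db$label, as.integer(f$counted),
      as.character(f$ci), as.integer(f$host_subtracted))
    body <- if (f$counted) paste(db$kmers, db$counts, sep = "\t") else db$kmers
    writeLines(c(header, body), path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(charToRaw("MFKD"), con)
    label_raw <- charToRaw(db$label)
    if (length(label_raw) > 255L)
      stop_format("label longer than 255 bytes")
    flags <- as.integer(f$counted) + 2L * as.integer(f$host_subtracted)
    ci_byte <- if (is.na(f$ci)) 255L else as.integer(f$ci)
    if (ci_byte > 255L) stop_format("ci larger than 255 not serializable")
    writeBin(as.raw(c(1L, db$k, level_to_code(f$level), flags, ci_byte,
                      length(label_raw))), con)
    writeBin(label_raw, con)
    n <- length(db$kmers)
    writeBin(as.integer(c(n %% 2^16, n %/% 2^16, 0L, 0L)), con,
             size = 2L, endian = "little")
    if (n > 0L) {
      writeBin(cpp_pack_kmers(db$kmers, db$k), con)
      if (f$counted)
        writeBin(as.integer(db$counts), con, size = 4L, endian = "little")
    }
  }
  invisible(path)
}

#' Read a k-mer database from disk
#'
#' The dialect is auto-detected from the leading bytes. A corrupt header,
#' a truncated payload, or a record inconsistent with the header's k
#' raises a format error.
#'
#' @param path File written by [save_kmer_db()].
#' @return The stored `kmer_counted_db` or `kmer_set`.
#' @export
load_kmer_db <- function(path) {
  if (!file.exists(path)) stop_format(sprintf("no such file: %s", path))
  head4 <- readBin(path, "raw", 4L)
  if (identical(rawToChar(head4), "MFKD")) {
    load_db_binary(path)
  } else if (identical(substr(rawToChar(head4), 1, 3), "#k=")) {
    load_db_text(path)
  } else {
    stop_format("unrecognized database file (bad magic)")
  }
}

load_db_text <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || !startsWith(lines[1], "#"))
    stop_format("missing text database header")
  fields <- strsplit(strsplit(sub("^#", "", lines[1]), "\t")[[1]], "=")
  vals <- setNames(vapply(fields, `[`, "", 2L),
                   vapply(fields, `[`, "", 1L))
  if (is.na(vals["k"])) stop_format("text database header lacks k")
  k <- as.integer(vals[["k"]])
  counted <- identical(vals[["counted"]], "1")
  label <- if ("label" %in% names(vals)) vals[["label"]] else ""
  level <- if ("level" %in% names(vals)) vals[["level"]] else NA_character_
  if (identical(level, "NA")) level <- NA_character_
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (counted) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    if (length(parts) && any(lengths(parts) != 2L))
      stop_format("counted text database rows must be KMER\\tCOUNT")
    kmers <- vapply(parts, `[`, "", 1L)
    counts <- as.integer(vapply(parts, `[`, "", 2L))
    if (any(is.na(counts)) || any(counts < 1L))
      stop_format("invalid count field")
  } else {
    kmers <- body
    counts <- NULL
  }
  if (length(kmers) && any(nchar(kmers) != k))
    stop_format("record length does not match header k")
  ci <- if ("ci" %in% names(vals)) suppressWarnings(as.integer(vals[["ci"]]))
        else NA_integer_
  hs <- identical(vals[["host_subtracted"]], "1")
  if (counted) {
    new_counted_db(kmers, counts, k, label, level)
  } else {
    new_kmer_set(kmers, k, label,
                 provenance = list(level = level, ci = ci,
                                   host_subtracted = hs))
  }
}

load_db_binary <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  need <- function(n, at) {
    if (length(raw) < at + n - 1L) stop_format("truncated database file")
    raw[at:(at + n - 1L)]
  }
  if (!identical(rawToChar(need(4L, 1L)), "MFKD"))
    stop_format("bad magic")
  version <- as.integer(need(1L, 5L))
  if (version != 1L) stop_format(sprintf("unsupported version %d", version))
  k <- as.integer(need(1L, 6L))
  if (k < 1L) stop_format("invalid k in header")
  level <- code_to_level(as.integer(need(1L, 7L)))
  flags <- as.integer(need(1L, 8L))
  counted <- bitwAnd(flags, 1L) > 0L
  hs <- bitwAnd(flags, 2L) > 0L
  ci_byte <- as.integer(need(1L, 9L))
  ci <- if (ci_byte == 255L) NA_integer_ else ci_byte
  label_len <- as.integer(need(1L, 10L))
  label <- if (label_len > 0L) rawToChar(need(label_len, 11L)) else ""
  pos <- 11L + label_len
  cnt16 <- readBin(need(8L, pos), "integer", 4L, size = 2L,
                   endian = "little", signed = FALSE)
  n <- cnt16[1] + cnt16[2] * 2^16 + cnt16[3] * 2^32 + cnt16[4] * 2^48
  pos <- pos + 8L
  bpk <- (k + 3L) %/% 4L
  expected <- pos - 1L + n * bpk + if (counted) 4L * n else 0L
  if (length(raw) != expected) stop_format("truncated database file")
  kmers <- if (n > 0L) {
    cpp_unpack_kmers(raw[pos:(pos + n * bpk - 1L)], k, as.integer(n))
  } else character(0)
  if (counted) {
    counts <- if (n > 0L) {
      readBin(raw[(pos + n * bpk):length(raw)], "integer", n, size = 4L,
              endian = "little")
    } else integer(0)
    new_counted_db(kmers, counts, k, label, level)
  } else {
    new_kmer_set(kmers, k, label,
                 provenance = list(level = level, ci = ci,
                                   host_subtracted = hs))
  }
}
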