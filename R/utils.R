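# Internal time helpers. All civil timestamps are carried as POSIXct in UTC:
# the methodology is defined entirely in local clock terms, so we store the
# local clock face in UTC and never apply timezone or DST arithmetic.

TS_FORMAT <- "%Y-%m-%dT%H:%M:%S"

parse_timestamp <- function(x) {
  as.POSIXct(as.character(x), tz = "UTC", format = TS_FORMAT)
}

format_timestamp <- function(ts) {
  format(ts, TS_FORMAT, tz = "UTC")
}

# Calendar date (UTC clock face) of a timestamp
ts_date <- function(ts) {
  as.IDate(as.integer(floor(as.numeric(ts) / 86400)))
}

# Minute of day in [0, 1439]
ts_minute <- function(ts) {
  as.integer(floor(as.numeric(ts) / 60) %% 1440L)
}

# "HH:MM" -> minutes after midnight
parse_clock_minutes <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3L) {
    stop("clock time must be 'HH:MM', got '", x, "'", call. = FALSE)
  }
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23L || mi > 59L) stop("clock time out of range: '", x, "'", call. = FALSE)
  h * 60L + mi
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# FNV-1a 32-bit hash of a character scalar, reported as 8 hex digits.
# Used only to stamp the run manifest with a configuration fingerprint.
fnv1a_hash <- function(x) {
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  }
  mul32 <- function(h, p) {  # (h * p) mod 2^32 without losing precision
    ((h %% 65536) * p + ((h %/% 65536 * p) %% 65536) * 65536) %% 4294967296
  }
  bytes <- utf8ToInt(enc2utf8(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    h <- mul32(xor32(h, b), 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Deterministic fwrite wrapper: fixed representation so identical tables
# produce byte-identical files across runs.
write_output_csv <- function(dt, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(dt, path, na = "", quote = FALSE,
                     logical01 = FALSE, scipen = 999)
  invisible(path)
}
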