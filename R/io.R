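# Plain-text input/output for every stage, plus schema validation with
# human-readable diagnostics.

#' Write / read a CPMG decay as two-column CSV
#'
#' Columns `time_s`, `signal`.
#'
#' @param decay a `cpmg_decay`.
#' @param path file path.
#' @return `read_decay_csv` returns a `cpmg_decay`-compatible list.
#' @export
write_decay_csv <- function(decay, path) {
  utils::write.csv(data.frame(time_s = decay$time, signal = decay$signal),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "signal") %in% names(d)))
    stop_param("decay CSV needs columns time_s, signal: ", path)
  structure(list(time = d$time_s, signal = d$signal), class = "cpmg_decay")
}

#' Write / read a melt curve as CSV (`temp_C`, `fluorescence`)
#' @param curve a `melt_curve`.
#' @param path file path.
#' @export
write_melt_csv <- function(curve, path) {
  utils::write.csv(data.frame(temp_C = curve$temperature,
                              fluorescence = curve$fluorescence),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_melt_csv
#' @export
read_melt_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("temp_C", "fluorescence") %in% names(d)))
    stop_param("melt CSV needs columns temp_C, fluorescence: ", path)
  structure(list(temperature = d$temp_C, fluorescence = d$fluorescence),
            class = "melt_curve")
}

#' Write / read peptide evidence as TSV
#' @param evidence evidence data.frame.
#' @param path file path.
#' @export
write_evidence_tsv <- function(evidence, path) {
  utils::write.table(evidence, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_evidence_tsv
#' @export
read_evidence_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "peptide", "expect", "sample", "compartment",
            "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_param("evidence TSV missing column(s) ", paste(miss, collapse = ", "),
               ": ", path)
  d
}

#' Write / read protein sequences as FASTA
#' @param sequences named character vector of sequences.
#' @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  lines <- unlist(lapply(names(sequences), function(id) {
    sq <- sequences[[id]]
    c(paste0(">", id),
      substring(sq, seq(1, nchar(sq), 60), pmin(seq(60, nchar(sq) + 59, 60),
                                                nchar(sq))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop_param("no FASTA records in ", path)
  ends <- c(hdr[-1] - 1L, length(lines))
  stats::setNames(
    vapply(seq_along(hdr), function(i)
      paste(lines[(hdr[i] + 1L):ends[i]], collapse = ""), ""),
    sub("^>", "", sub("\\s.*$", "", lines[hdr])))
}

#' Validate input files against the pipeline's schemas
#'
#' Checks each file by extension-independent schema name: decay CSVs need
#' numeric, strictly increasing `time_s`; melt CSVs need a strictly
#' increasing `temp_C` grid; evidence TSVs need the six evidence columns with
#' non-negative expect scores; FASTA files must contain only the 20
#' amino-acid letters.
#'
#' @param files named character vector: names are schemas (`"decay"`,
#'   `"melt"`, `"evidence"`, `"fasta"`), values are paths.
#' @return data.frame `file`, `schema`, `ok`, `message`; one row per file.
#' @export
validate_io <- function(files) {
  check_one <- function(schema, path) {
    if (!file.exists(path)) return(paste0("file not found: ", path))
    tryCatch({
      switch(schema,
        decay = {
          d <- utils::read.csv(path)
          if (!all(c("time_s", "signal") %in% names(d)))
            return("missing columns time_s/signal")
          if (!is.numeric(d$time_s) || !is.numeric(d$signal))
            return("non-numeric time_s/signal")
          bad <- which(diff(d$time_s) <= 0)
          if (length(bad))
            return(paste0("time_s not strictly increasing at row ", bad[1] + 1))
          "ok"
        },
        melt = {
          d <- utils::read.csv(path)
          if (!all(c("temp_C", "fluorescence") %in% names(d)))
            return("missing columns temp_C/fluorescence")
          bad <- which(diff(d$temp_C) <= 0)
          if (length(bad))
            return(paste0("temp_C not strictly increasing at row ", bad[1] + 1))
          "ok"
        },
        evidence = {
          d <- utils::read.delim(path)
          need <- c("protein_id", "peptide", "expect", "sample",
                    "compartment", "replicate")
          miss <- setdiff(need, names(d))
          if (length(miss))
            return(paste0("missing column(s) ", paste(miss, collapse = ", ")))
          if (any(d$expect < 0)) return("negative expect score")
          "ok"
        },
        fasta = {
          sqs <- read_fasta(path)
          for (id in names(sqs)) {
            res <- strsplit(sqs[[id]], "")[[1]]
            bad <- which(!res %in% names(AA_MONO))
            if (length(bad))
              return(paste0("illegal residue '", res[bad[1]], "' in record ", id))
          }
          "ok"
        },
        paste0("unknown schema '", schema, "'"))
    }, error = function(e) paste0("parse error: ", conditionMessage(e)))
  }
  msgs <- vapply(seq_along(files), function(i)
    check_one(names(files)[i], files[[i]]), "")
  data.frame(file = unname(unlist(files)), schema = names(files),
             ok = msgs == "ok", message = msgs)
}
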