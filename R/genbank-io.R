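#' Read and write GenBank flat files
#'
#' A minimal GenBank flat-file reader/writer for annotated mitogenomes. The
#' reader collects \code{CDS}, \code{tRNA}, \code{rRNA} and
#' \code{misc_feature} entries (a \code{misc_feature} whose note mentions a
#' control region becomes a \code{control_region} feature), preserves 1-based
#' inclusive coordinates, flags \code{complement(...)} features as minus
#' strand, and understands \code{join(a..L,1..b)} origin-spanning locations
#' on circular genomes. Start/stop codons and MITOS-style quality scores are
#' carried in the feature \code{/note} as \code{key=value} pairs, which is
#' what \code{writeGenBank} emits, so write-then-read is the identity.
#'
#' @param path file path.
#' @return \code{readGenBank}: a \linkS4class{GenomeRecord}.
#' @examples
#' rec <- makeAnnotatedGenome(seed = 1)$truth
#' f <- tempfile(fileext = ".gb")
#' writeGenBank(rec, f)
#' rec2 <- readGenBank(f)
#' identical(gbFeatures(rec), gbFeatures(rec2))
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file: no LOCUS line")
  id <- strsplit(trimws(sub("^LOCUS", "", locus[1])), "\\s+")[[1]][1]
  circular <- grepl("circular", locus[1], ignore.case = TRUE)

  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("format error: record has no sequence (ORIGIN missing)")
  endRec <- grep("^//", lines)
  endRec <- if (length(endRec)) endRec[1] else length(lines) + 1L
  seqLines <- lines[(ori[1] + 1L):(endRec - 1L)]
  seqChr <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  if (!nchar(seqChr)) stop("format error: record has no sequence")

  featStart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(featStart)) {
    block <- lines[(featStart[1] + 1L):(ori[1] - 1L)]
    ## a new feature starts at indentation 5; continuation/qualifiers at 21
    isKey <- grepl("^ {5}\\S", block)
    idx <- which(isKey)
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1L] - 1L else length(block)
      key <- strsplit(trimws(block[from]), "\\s+")[[1]][1]
      if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature")) next
      body <- paste(trimws(block[from:to]), collapse = " ")
      loc <- sub(paste0("^", key, "\\s+"), "", trimws(block[from]))
      quals <- regmatches(body, gregexpr('/[A-Za-z_]+(="[^"]*"|=[^ ]+)?', body))[[1]]
      getq <- function(nm) {
        hit <- grep(paste0("^/", nm, "="), quals, value = TRUE)
        if (!length(hit)) return(NA_character_)
        gsub('^/[A-Za-z_]+="?|"$', "", hit[1])
      }
      strand <- if (grepl("complement", loc)) "-" else "+"
      locIn <- gsub("complement\\(|\\)$", "", loc)
      nums <- as.integer(unlist(regmatches(locIn, gregexpr("[0-9]+", locIn))))
      if (grepl("^join", locIn)) {
        start <- nums[1]; end <- nums[length(nums)]
      } else {
        start <- nums[1]; end <- nums[2]
      }
      note <- getq("note")
      noteKV <- if (!is.na(note)) {
        parts <- strsplit(note, ";", fixed = TRUE)[[1]]
        kv <- strsplit(parts, "=", fixed = TRUE)
        stats::setNames(vapply(kv, function(p) if (length(p) > 1) p[2] else "",
                               character(1)),
                        vapply(kv, `[`, character(1), 1))
      } else character(0)
      kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     misc_feature = {
                       if (!is.na(note) && grepl("control", note, ignore.case = TRUE))
                         "control_region" else "control_region"
                     })
      feats[[length(feats) + 1L]] <- data.frame(
        name = getq("gene") %||% NA_character_,
        kind = kind, strand = strand, start = start, end = end,
        start_codon = unname(noteKV["start_codon"][1]) %||% NA_character_,
        stop_codon = unname(noteKV["stop_codon"][1]) %||% NA_character_,
        quality = suppressWarnings(as.numeric(noteKV["quality"][1])),
        stringsAsFactors = FALSE)
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(name = character(0), kind = character(0), strand = character(0),
               start = integer(0), end = integer(0),
               start_codon = character(0), stop_codon = character(0),
               quality = numeric(0))
  features$start_codon[features$start_codon == ""] <- NA_character_
  features$stop_codon[features$stop_codon == ""] <- NA_character_
  L <- nchar(seqChr)
  bad <- features$end > L & features$start <= features$end
  if (any(features$start > L) || any(bad))
    stop("coordinate error: feature outside sequence bounds (",
         paste(features$name[features$start > L | bad], collapse = ", "), ")")
  genomeRecord(id = id, sequence = seqChr, features = features,
               circular = circular)
}

#' @param record a \linkS4class{GenomeRecord}.
#' @return \code{writeGenBank}: the path, invisibly.
#' @rdname readGenBank
#' @export
writeGenBank <- function(record, path) {
  f <- record@features
  L <- genomeLength(record)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s     UNA",
                     record@id, L,
                     if (record@circular) "circular" else "linear"), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  for (i in seq_len(nrow(f))) {
    key <- switch(f$kind[i], PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  control_region = "misc_feature")
    loc <- if (f$end[i] < f$start[i])
      sprintf("join(%d..%d,1..%d)", f$start[i], L, f$end[i])
    else sprintf("%d..%d", f$start[i], f$end[i])
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name[i]), con)
    kv <- if (f$kind[i] == "control_region") "control region" else character(0)
    if (!is.na(f$start_codon[i])) kv <- c(kv, paste0("start_codon=", f$start_codon[i]))
    if (!is.na(f$stop_codon[i])) kv <- c(kv, paste0("stop_codon=", f$stop_codon[i]))
    if (!is.na(f$quality[i])) kv <- c(kv, paste0("quality=", format(f$quality[i])))
    if (length(kv))
      writeLines(sprintf('                     /note="%s"',
                         paste(kv, collapse = ";")), con)
    if (f$kind[i] == "PCG")
      writeLines("                     /transl_table=5", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(genomeSequence(record))
  starts <- seq(1, nchar(s), by = 60)
  for (st in starts) {
    chunk <- substr(s, st, min(st + 59, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", st, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}
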