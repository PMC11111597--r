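# Pluggable transcription backends. Production deployments send audio to a
# cloud speech-to-text service; here the interface is a small S3 generic
# with two offline backends: a mock (fixed id -> text map, for tests) and a
# file backend that reads a sidecar .txt next to each WAV.

#' Mock transcription backend
#'
#' Returns canned transcripts from a fixed map of utterance id to text.
#'
#' @param map Named character vector mapping utterance ids to transcripts.
#' @return A transcriber backend.
#' @export
mock_transcriber <- function(map) {
  if (!is.character(map) || is.null(names(map)) || !all(nzchar(names(map))))
    vs_config("map must be a named character vector (id -> transcript)")
  structure(list(map = map), class = c("mock_transcriber", "transcriber"))
}

#' Sidecar-file transcription backend
#'
#' Reads the transcript from a `.txt` file next to the audio file
#' (`foo.wav` -> `foo.txt`).
#'
#' @return A transcriber backend.
#' @export
file_transcriber <- function() {
  structure(list(), class = c("file_transcriber", "transcriber"))
}

#' Transcribe an utterance through a backend
#'
#' @param backend A transcriber backend ([mock_transcriber()] or
#'   [file_transcriber()]).
#' @param x Utterance reference understood by the backend: an id for the
#'   mock backend, a WAV path for the file backend.
#' @return Transcript text.
#' @export
transcribe <- function(backend, x) {
  if (!inherits(backend, "transcriber"))
    vs_config("no transcriber backend registered")
  UseMethod("transcribe")
}

#' @export
transcribe.mock_transcriber <- function(backend, x) {
  if (!x %in% names(backend$map))
    vs_transcription(sprintf("mock transcriber has no entry for id '%s'", x))
  unname(backend$map[[x]])
}

#' @export
transcribe.file_transcriber <- function(backend, x) {
  txt_path <- paste0(tools::file_path_sans_ext(x), ".txt")
  if (!file.exists(txt_path))
    vs_transcription(sprintf("sidecar transcript not found: %s", txt_path))
  paste(readLines(txt_path, warn = FALSE, encoding = "UTF-8"),
        collapse = " ")
}
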