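#' Write / read a session container
#'
#' Sessions are stored as a schema-versioned hierarchical R object
#' (native serialization), so numeric arrays round-trip bit-exactly and
#' ragged spike trains need no padding.  Unknown top-level groups are
#' preserved.  Reading a container whose minor schema version is newer
#' than the package's succeeds with a warning; a different major
#' version, or a container missing required groups, is an error with a
#' migration hint.
#'
#' @param session a `session_recording` (see [gen_session()]).
#' @param path file path.
#' @return `write_session` returns `path` invisibly; `read_session`
#'   returns the validated `session_recording`.
#' @export
write_session <- function(session, path) {
  validate_session(session)
  if (is.null(session$schema_version))
    session$schema_version <- SESSION_SCHEMA_VERSION
  saveRDS(session, path)
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  session <- readRDS(path)
  ver <- session$schema_version
  if (is.null(ver))
    stop("read_session: container has no schema version; ",
         "re-export it with write_session()")
  cur <- as.integer(strsplit(SESSION_SCHEMA_VERSION, ".", fixed = TRUE)[[1]])
  got <- as.integer(strsplit(as.character(ver), ".", fixed = TRUE)[[1]])
  if (got[1] != cur[1])
    stop("read_session: schema major version ", ver, " != ",
         SESSION_SCHEMA_VERSION, "; migrate the container before reading")
  if (length(got) > 1 && got[2] > cur[2])
    warning("read_session: container schema ", ver,
            " is newer than supported ", SESSION_SCHEMA_VERSION,
            "; unknown groups are preserved but ignored")
  validate_session(session)
  session
}

#' Adapter stub for the public wheel-running dataset deposit
#'
#' Documented interface for mapping the original public archive (per-rat
#' LFP channels, spike times with cell-type labels, speed traces, and
#' trial tables) into a `session_recording`, so real recordings can be
#' plugged into the analysis modules without touching them.  Loading
#' the deposit itself is out of scope for this package; this stub
#' defines the expected mapping and fails with a clear message.
#'
#' @param path path to a deposit directory.
#' @return (never returns) a `session_recording` once implemented.
#' @export
read_dryad_session <- function(path) {
  stop("read_dryad_session: adapter not implemented. Expected mapping:\n",
       "  <deposit>/lfp.*      -> session$lfp (uV) + session$fs_lfp\n",
       "  <deposit>/speed.*    -> session$speed (cm/s) + session$fs_beh\n",
       "  <deposit>/spikes/*   -> session$neurons (id, cell_type, spike_times)\n",
       "  <deposit>/trials.*   -> session$trials (t_start, t_end, context,\n",
       "                          choice, condition)\n",
       "Construct the list, set schema_version = \"", SESSION_SCHEMA_VERSION,
       "\", and pass it through validate_session().")
}
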