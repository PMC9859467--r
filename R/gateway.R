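#' In-memory participant/measurement store
#'
#' Backs the mock IoT gateway: two tables, one holding participant identity
#' records (ID number and name) and one holding the uploaded BrAC
#' measurements, mirroring the device's cloud database design. The store is
#' an environment, so handlers mutate it by reference.
#'
#' @param participants Optional data frame with columns `participant_id`
#'   (digit strings, unique) and `name`.
#' @return An object of class `brac_store`.
#' @export
#' @examples
#' store <- brac_store(data.frame(participant_id = "1001", name = "Alice"))
#' lookup_participant(store, "1001")
brac_store <- function(participants = NULL) {
  store <- new.env(parent = emptyenv())
  store$participants <- data.frame(participant_id = character(),
                                   name = character())
  store$measurements <- data.frame(participant_id = character(),
                                   brac = numeric(),
                                   timestamp = character())
  class(store) <- "brac_store"
  if (!is.null(participants))
    for (i in seq_len(nrow(participants)))
      add_participant(store, participants$participant_id[i],
                      participants$name[i])
  store
}

#' Register a participant in the store
#'
#' @param store A [brac_store()].
#' @param participant_id Non-empty digit string, unique within the store.
#' @param name Participant name.
#' @export
add_participant <- function(store, participant_id, name) {
  check_participant_id(participant_id)
  if (participant_id %in% store$participants$participant_id)
    stop("participant_id '", participant_id, "' already exists", call. = FALSE)
  store$participants <- rbind(
    store$participants,
    data.frame(participant_id = participant_id, name = name))
  invisible(store)
}

check_participant_id <- function(id) {
  if (length(id) != 1 || is.na(id) || !nzchar(id) || !grepl("^[0-9]+$", id))
    stop("participant_id must be a non-empty digit string", call. = FALSE)
  invisible(id)
}

# --- transport abstraction -------------------------------------------------
# A transport is a function(request_string) -> list(status, body) where the
# request string is a GET-style path with an URL-encoded query
# ("get_name?id=1001"). The in-process transport parses the query string and
# dispatches to the two endpoint handlers, standing in for the two
# server-side scripts at unique addresses.

#' In-process transport over a store
#'
#' @param store A [brac_store()].
#' @return A transport function (see Details in [lookup_participant()]).
#' @export
in_process_transport <- function(store) {
  force(store)
  function(request) {
    parsed <- parse_request(request)
    switch(parsed$path,
      get_name = handle_get_name(store, parsed$params),
      insert = handle_insert(store, parsed$params),
      list(status = 404L, body = "NO SUCH ENDPOINT")
    )
  }
}

build_request <- function(path, params) {
  query <- paste(names(params),
                 vapply(params, function(v) utils::URLencode(as.character(v),
                                                             reserved = TRUE),
                        character(1)),
                 sep = "=", collapse = "&")
  paste0(path, "?", query)
}

parse_request <- function(request) {
  parts <- strsplit(request, "?", fixed = TRUE)[[1]]
  params <- list()
  if (length(parts) > 1 && nzchar(parts[2])) {
    for (kv in strsplit(parts[2], "&", fixed = TRUE)[[1]]) {
      kv <- strsplit(kv, "=", fixed = TRUE)[[1]]
      params[[kv[1]]] <- utils::URLdecode(kv[2])
    }
  }
  list(path = parts[1], params = params)
}

handle_get_name <- function(store, params) {
  id <- params$id
  hit <- store$participants$name[store$participants$participant_id == id]
  if (length(hit) == 0) list(status = 404L, body = "NOT FOUND")
  else list(status = 200L, body = hit[1])
}

handle_insert <- function(store, params) {
  id <- params$id
  brac <- suppressWarnings(as.numeric(params$brac))
  if (is.na(brac) || brac < 0)
    return(list(status = 400L, body = "INVALID BRAC"))
  if (!id %in% store$participants$participant_id)
    return(list(status = 404L, body = "NOT FOUND"))
  store$measurements <- rbind(
    store$measurements,
    data.frame(participant_id = id, brac = brac,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")))
  list(status = 200L, body = "OK")
}

#' Look up a participant's name by ID
#'
#' First request of the device flow: the ID number entered on the keypad is
#' sent as a GET-style request (`get_name?id=<ID>`) and the stored name
#' comes back for on-screen confirmation. An unknown ID yields a `NULL`
#' (the device re-prompts rather than crashing); an empty or non-digit ID
#' is rejected before any transport call.
#'
#' @param store A [brac_store()] (used to build the default transport).
#' @param participant_id Digit string.
#' @param transport Optional transport function; defaults to
#'   [in_process_transport()] over `store`.
#' @return The participant's name, or `NULL` if not found.
#' @export
lookup_participant <- function(store, participant_id,
                               transport = in_process_transport(store)) {
  check_participant_id(participant_id)
  resp <- transport(build_request("get_name", list(id = participant_id)))
  if (resp$status != 200L) NULL else resp$body
}

#' Upload a BrAC measurement
#'
#' Second request of the device flow: the quantified BrAC is sent together
#' with the previously confirmed participant ID (`insert?id=<ID>&
#' brac=<value>`) and appended to the measurements table; the store adds the
#' timestamp on insert.
#'
#' @inheritParams lookup_participant
#' @param brac Measured BrAC in mcg/100 mL, non-negative.
#' @return `TRUE` invisibly on acknowledgement; errors on rejection.
#' @export
upload_measurement <- function(store, participant_id, brac,
                               transport = in_process_transport(store)) {
  check_participant_id(participant_id)
  if (!is.numeric(brac) || length(brac) != 1 || is.na(brac) || brac < 0)
    stop("`brac` must be a single non-negative number", call. = FALSE)
  resp <- transport(build_request("insert",
                                  list(id = participant_id, brac = brac)))
  if (resp$status != 200L)
    stop("upload rejected: ", resp$body, call. = FALSE)
  invisible(TRUE)
}

#' Measurements stored for a participant
#'
#' @param store A [brac_store()].
#' @param participant_id Optional filter.
#' @return The measurements data frame.
#' @export
list_measurements <- function(store, participant_id = NULL) {
  m <- store$measurements
  if (!is.null(participant_id))
    m <- m[m$participant_id == participant_id, , drop = FALSE]
  m
}

#' Run one device session
#'
#' The state machine a single breath test goes through: read the entered ID,
#' look up the name, and — only upon confirmation — quantify the breath
#' trace and upload the result. A rejected confirmation aborts with nothing
#' persisted; an unknown ID ends the session before any measurement is
#' taken. A transport failure aborts the session as retryable, persisting
#' nothing.
#'
#' @param store A [brac_store()].
#' @param id_input The ID string entered on the keypad.
#' @param confirm Logical: does the user confirm the displayed name?
#' @param trace The [sensor_trace()] from the breath sample.
#' @param model The [fit_calibration()] model.
#' @param params [threshold_params()] for the zero classifier.
#' @param transport Optional transport; defaults to in-process over `store`.
#' @return A list with `outcome` (`"uploaded"`, `"aborted"`, `"not_found"`
#'   or `"error"`), and when uploaded, `name` and `brac`.
#' @export
run_session <- function(store, id_input, confirm, trace, model,
                        params = threshold_params(),
                        transport = in_process_transport(store)) {
  name <- tryCatch(lookup_participant(store, id_input, transport),
                   error = function(e) {
                     structure(conditionMessage(e), class = "session_error")
                   })
  if (inherits(name, "session_error"))
    return(list(outcome = "error", message = unclass(name), retryable = TRUE))
  if (is.null(name)) return(list(outcome = "not_found"))
  if (!isTRUE(confirm)) return(list(outcome = "aborted", name = name))
  reading <- quantify(trace, model, params)
  ok <- tryCatch(
    upload_measurement(store, id_input, reading$value, transport),
    error = function(e) e)
  if (inherits(ok, "error"))
    return(list(outcome = "error", message = conditionMessage(ok),
                retryable = TRUE))
  list(outcome = "uploaded", name = name, brac = reading$value,
       is_zero_classified = reading$is_zero_classified)
}

#' Save / load a store as JSON
#'
#' Serializes both tables; reloading gives identical query results.
#'
#' @param store A [brac_store()].
#' @param path File path.
#' @return `read_store()` returns a [brac_store()]; `write_store()` returns
#'   `path` invisibly.
#' @export
write_store <- function(store, path) {
  jsonlite::write_json(
    list(participants = store$participants,
         measurements = store$measurements),
    path, dataframe = "rows", digits = I(17))
  invisible(path)
}

#' @rdname write_store
#' @export
read_store <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  store <- brac_store()
  if (length(x$participants))
    store$participants <- data.frame(
      participant_id = as.character(x$participants$participant_id),
      name = as.character(x$participants$name))
  if (length(x$measurements))
    store$measurements <- data.frame(
      participant_id = as.character(x$measurements$participant_id),
      brac = as.numeric(x$measurements$brac),
      timestamp = as.character(x$measurements$timestamp))
  store
}
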