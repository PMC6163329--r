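; Minimal kitchen domain: one takeable object, a handful of locations.
; A person may hold at most 3 objects at a time.
(define (domain toy_kitchen)
  (:types takeable location place - object)
  (:objects knife - takeable
            drawer board counter hands - location
            kitchen - place)
  (:functions (is-at ?what - takeable) - location
              (objects_taken) - number
              (is-open ?l - location) - boolean
              (at-person) - place)
  (:init
    (= (is-at knife) drawer)
    (= (objects_taken) 0)
    (= (is-open drawer) true)
    (= (is-open board) true)
    (= (is-open counter) true)
    (= (at-person) kitchen)
  )
  (:action take
    :parameters (?what - takeable ?from - location)
    :precondition (and (= (is-at ?what) ?from)
                       (= (is-open ?from) true)
                       (< (objects_taken) 3))
    :effect (and (assign (is-at ?what) hands)
                 (increase (objects_taken) 1))
    :label "take-{what}-{from}")
  (:action put
    :parameters (?what - takeable ?to - location)
    :precondition (and (= (is-at ?what) hands)
                       (= (is-open ?to) true))
    :effect (and (assign (is-at ?what) ?to)
                 (decrease (objects_taken) 1))
    :label "put-{what}-{to}")
  (:action walk
    :parameters (?from - place ?to - place)
    :precondition (= (at-person) ?from)
    :effect (assign (at-person) ?to)
    :label "walk-{from}-{to}")
)
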