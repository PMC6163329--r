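; Toy sandwich domain.  12 action classes: the brownie set plus cut
; (bread and tomato can be cut); no pooled objects here.
(define (domain sandwich)
  (:types thing location place substance device - object
          takeable source - thing
          container pourable cuttable - takeable
          openable - location)
  (:objects plate - container
            knife - takeable
            bread tomato - cuttable
            peanut_butter_jar jam_jar - pourable
            faucet - source
            counter sink hands - location
            cupboard_tl fridge - openable
            counter_place fridge_place - place
            peanut_butter jam water - substance
            toaster - device)
  (:functions (is-at ?what - takeable) - location
              (at-person) - place
              (objects_taken) - number
              (is-open ?l - location) - boolean
              (is-on ?d - device) - boolean
              (contains ?c - container ?s - substance) - boolean
              (stirred ?c - container) - boolean
              (cleaned ?t - takeable) - boolean
              (is-cut ?c - cuttable) - boolean
              (can-pour ?f - thing ?s - substance) - boolean)
  (:init
    (= (is-at plate) cupboard_tl)
    (= (is-at knife) cupboard_tl)
    (= (is-at bread) counter)
    (= (is-at tomato) fridge)
    (= (is-at peanut_butter_jar) cupboard_tl)
    (= (is-at jam_jar) fridge)
    (= (at-person) counter_place)
    (= (objects_taken) 0)
    (= (is-open counter) true)
    (= (is-open sink) true)
    (can-pour faucet water)
    (can-pour peanut_butter_jar peanut_butter)
    (can-pour jam_jar jam)
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
  (:action open
    :parameters (?o - openable)
    :precondition (= (is-open ?o) false)
    :effect (assign (is-open ?o) true)
    :label "open-{o}")
  (:action close
    :parameters (?o - openable)
    :precondition (= (is-open ?o) true)
    :effect (assign (is-open ?o) false)
    :label "close-{o}")
  (:action walk
    :parameters (?from - place ?to - place)
    :precondition (= (at-person) ?from)
    :effect (assign (at-person) ?to)
    :label "walk-{from}-{to}")
  (:action turn_on
    :parameters (?d - device)
    :precondition (= (is-on ?d) false)
    :effect (assign (is-on ?d) true)
    :label "turn_on-{d}")
  (:action fill
    :parameters (?what - substance ?from - thing ?to - container)
    :precondition (= (can-pour ?from ?what) true)
    :effect (assign (contains ?to ?what) true)
    :label "fill-{what}-{from}-{to}")
  (:action clean
    :parameters (?t - takeable)
    :effect (assign (cleaned ?t) true)
    :label "clean-{t}")
  (:action stir
    :parameters (?c - container)
    :effect (assign (stirred ?c) true)
    :label "stir-{c}")
  (:action shake
    :parameters (?c - container)
    :effect (and)
    :label "shake-{c}")
  (:action cut
    :parameters (?w - cuttable)
    :precondition (not (= (is-at ?w) hands))
    :effect (assign (is-cut ?w) true)
    :label "cut-{w}")
  (:action other
    :parameters ()
    :effect (and)
    :label "other")
)
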