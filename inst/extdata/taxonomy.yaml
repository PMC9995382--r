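- label: invitation_broad
  code: 0
  category: recommended
  description: Open-ended and non-suggestive questions that elicit free narrative
    from children.
- label: invitation_focus
  code: 1
  category: recommended
  description: Open-ended and non-suggestive questions that elicit narrative about
    the focused topic from children.
- label: facilitator
  code: 2
  category: recommended
  description: Non-suggestive utterances that promote further narrative about content
    previously mentioned.
- label: directive
  code: 3
  category: recommended
  description: Questions that focus the children's attention on content the child
    has already mentioned for further explanation.
- label: clarification
  code: 4
  category: recommended
  description: Attempts to clarify what the child has said.
- label: option_posing
  code: 5
  category: not_recommended
  description: Closed questions that focus the children's attention on content the
    child has not yet mentioned without implying a specific type of answer.
- label: specific_suggestive
  code: 6
  category: not_recommended
  description: Questions that indicate what kind of answer is expected by assuming
    details that children have not mentioned.
- label: unspecific_suggestive
  code: 7
  category: not_recommended
  description: Questions that indicate what kind of answer is expected without assuming
    details that children have not mentioned.
- label: repetition
  code: 8
  category: not_recommended
  description: Questions continuously asking what the interviewer has already asked.
- label: inappropriate_utterance
  code: 9
  category: not_recommended
  description: Questions not appropriate for eliciting correct information from children
    (multiple details at once, difficult words, unclear grammar, temporal estimates,
    fantasy).
- label: multiple_choice
  code: 10
  category: not_recommended
  description: Questions that focus the children's attention on specific answers,
    or force them to choose among options.
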