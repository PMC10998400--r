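# Final validated questionnaire: 30 questions, 43 items, five parts.
version_label: final
provenance: final_questionnaire
parts:
  - part_id: part1
    title: "Caregiver and practice data"
    ranking_depth: 5
    questions:
      - question_id: "1"
        text: "What role do you assume as a caregiver?"
        response_format: categorical
      - question_id: "2"
        text: "How long have you been professionally active as a healthcare provider?"
        response_format: numeric_band
      - question_id: "3"
        text: "What is your gender?"
        response_format: categorical
      - question_id: "4"
        text: "Where is your practice located?"
        response_format: categorical
      - question_id: "5"
        text: "What type of practice do you mainly work in?"
        response_format: categorical
      - question_id: "6"
        text: "What payment system do you work with?"
        response_format: categorical
      - question_id: "7"
        text: "Does your practice or team employ a practice assistant and/or administrative assistant?"
        response_format: categorical
      - question_id: "8"
        text: "Does your practice currently employ a trainee general practitioner?"
        response_format: categorical
      - question_id: "9"
        text: "How many in-person patient contacts do you have per health care provider on an average weekday?"
        response_format: numeric_band
      - question_id: "10"
        text: "Did you participate at least once in the Audit?"
        response_format: categorical
      - question_id: "11"
        text: "Why did you not participate in the Audit?"
        response_format: open
  - part_id: part2_1
    title: "Purpose of the survey"
    ranking_depth: 3
    questions:
      - question_id: "12"
        text: "Please indicate the extent to which you agree with the following statements:"
        response_format: likert_agreement
        items:
          - item_id: "12.1"
            text: "The purpose of the Audit is clear to me."
          - item_id: "12.2"
            text: "I find the purpose of the Audit relevant to the work I do today."
          - item_id: "12.3"
            text: "I find that using the Audit positively affects my current way of working."
  - part_id: part2_2
    title: "Collection of data through the EHR"
    ranking_depth: 5
    questions:
      - question_id: "13"
        text: "How satisfied are you with the way the data was collected?"
        response_format: satisfaction
      - question_id: "14"
        text: "How could we improve the way we collect data?"
        response_format: open
      - question_id: "15"
        text: "I feel that the data and results retrieved are an accurate representation of my practice."
        response_format: likert_agreement
      - question_id: "16"
        text: "How satisfied are you with the frequency of data retrieval?"
        response_format: satisfaction
      - question_id: "17"
        text: "How frequently would you like to participate in the Audit?"
        response_format: categorical
      - question_id: "18"
        text: "I find participation in the Audit time consuming."
        response_format: likert_agreement
  - part_id: part2_3
    title: "Get feedback"
    ranking_depth: 5
    questions:
      - question_id: "19"
        text: "How frequently did you use the feedback?"
        response_format: categorical
      - question_id: "20"
        text: "Why did you never look at the feedback?"
        response_format: open
      - question_id: "21"
        text: "Please indicate the extent to which you are satisfied:"
        response_format: satisfaction
        items:
          - item_id: "21.1"
            text: "How satisfied are you about how feedback is given (in general)?"
          - item_id: "21.2"
            text: "How satisfied are you about the frequency of the feedback?"
          - item_id: "21.3"
            text: "How satisfied are you about getting feedback per practice, as opposed to per individual physician?"
          - item_id: "21.4"
            text: "How satisfied are you about the way the performance level of the practice is displayed?"
          - item_id: "21.5"
            text: "How satisfied are you about the content of the feedback?"
          - item_id: "21.6"
            text: "How satisfied are you about the possibility to compare the performance level of the practice with others (benchmarking)?"
      - question_id: "22"
        text: "Please indicate the extent to which you agree with the following statements:"
        response_format: likert_agreement
        items:
          - item_id: "22.1"
            text: "I find the feedback given relevant to achieving a better level of performance."
          - item_id: "22.2"
            text: "I find it useful that the current level of performance is shown in relation to the previous level."
          - item_id: "22.3"
            text: "I find the way a feedback report can be viewed user-friendly."
      - question_id: "23"
        text: "Did you set up any type of quality improvement project in your practice based on the feedback provided?"
        response_format: categorical
      - question_id: "24"
        text: "Why did you/ didn't you set up a quality improvement project?"
        response_format: open
      - question_id: "25"
        text: "Please indicate the extent to which you agree with the following statements:"
        response_format: likert_agreement
        items:
          - item_id: "25.1"
            text: "I find the effort I have to put into reviewing the feedback negligible."
          - item_id: "25.2"
            text: "I am satisfied with the amount of feedback given."
          - item_id: "25.3"
            text: "The feedback should contain written advice that aims to improve my performance level."
          - item_id: "25.4"
            text: "If I received the feedback directly in my EHR (push system), I would use it more frequently."
          - item_id: "25.5"
            text: "The feedback provided aims to support me in improving the performance level of my practice."
  - part_id: part2_4
    title: "Co-interventions"
    ranking_depth: 5
    questions:
      - question_id: "26"
        text: "A discussion with other GPs regarding the feedback received seems a useful addition."
        response_format: likert_agreement
      - question_id: "27"
        text: "How satisfied are you regarding the support on using the Audit and getting feedback?"
        response_format: satisfaction
      - question_id: "28"
        text: "How satisfied are you with the way questions and problems related to the audit were resolved?"
        response_format: satisfaction
      - question_id: "29"
        text: "The reminder helped me participate in the Audit."
        response_format: likert_agreement
      - question_id: "30"
        text: "Is there anything else you would like to mention?"
        response_format: open
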