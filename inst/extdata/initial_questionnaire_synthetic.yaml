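version_label: draft_v1
provenance: drafting
parts:
- part_id: part1
  title: Part 1
  ranking_depth: 5
  questions:
  - question_id: '1'
    text: Question 1
    response_format: likert_agreement
    items:
    - item_id: '1'
      text: Question 1
      origin: panel_added
  - question_id: '2'
    text: Question 2
    response_format: likert_agreement
    items:
    - item_id: '2'
      text: Question 2
      origin: panel_added
  - question_id: '3'
    text: Question 3
    response_format: likert_agreement
    items:
    - item_id: '3'
      text: Question 3
      origin: panel_added
  - question_id: '4'
    text: Question 4
    response_format: likert_agreement
    items:
    - item_id: '4'
      text: Question 4
      origin: panel_added
  - question_id: '5'
    text: Question 5
    response_format: likert_agreement
    items:
    - item_id: '5'
      text: Question 5
      origin: panel_added
  - question_id: '6'
    text: Question 6
    response_format: likert_agreement
    items:
    - item_id: '6'
      text: Question 6
      origin: panel_added
  - question_id: '7'
    text: Question 7
    response_format: likert_agreement
    items:
    - item_id: '7'
      text: Question 7
      origin: panel_added
  - question_id: '8'
    text: Question 8
    response_format: likert_agreement
    items:
    - item_id: '8'
      text: Question 8
      origin: panel_added
  - question_id: '9'
    text: Question 9
    response_format: likert_agreement
    items:
    - item_id: '9'
      text: Question 9
      origin: panel_added
  - question_id: '10'
    text: Question 10
    response_format: likert_agreement
    items:
    - item_id: '10'
      text: Question 10
      origin: panel_added
  - question_id: '11'
    text: Question 11
    response_format: likert_agreement
    items:
    - item_id: '11'
      text: Question 11
      origin: panel_added
- part_id: part2_1
  title: Part 2_1
  ranking_depth: 3
  questions:
  - question_id: '12'
    text: Question 12
    response_format: likert_agreement
    items:
    - item_id: '12.1'
      text: Sub-item 1 of question 12
      origin: cp_fit
    - item_id: '12.2'
      text: Sub-item 2 of question 12
      origin: cp_fit
    - item_id: '12.3'
      text: Sub-item 3 of question 12
      origin: cp_fit
  - question_id: '13'
    text: Question 13
    response_format: likert_agreement
    items:
    - item_id: '13'
      text: Question 13
      origin: panel_added
  - question_id: '14'
    text: Question 14
    response_format: likert_agreement
    items:
    - item_id: '14.1'
      text: Sub-item 1 of question 14
      origin: cp_fit
    - item_id: '14.2'
      text: Sub-item 2 of question 14
      origin: cp_fit
    - item_id: '14.3'
      text: Sub-item 3 of question 14
      origin: cp_fit
    - item_id: '14.4'
      text: Sub-item 4 of question 14
      origin: cp_fit
    - item_id: '14.5'
      text: Sub-item 5 of question 14
      origin: cp_fit
  - question_id: '15'
    text: Question 15
    response_format: likert_agreement
    items:
    - item_id: '15'
      text: Question 15
      origin: panel_added
- part_id: part2_2
  title: Part 2_2
  ranking_depth: 5
  questions:
  - question_id: '16'
    text: Question 16
    response_format: likert_agreement
    items:
    - item_id: '16'
      text: Question 16
      origin: panel_added
  - question_id: '17'
    text: Question 17
    response_format: likert_agreement
    items:
    - item_id: '17'
      text: Question 17
      origin: panel_added
  - question_id: '18'
    text: Question 18
    response_format: likert_agreement
    items:
    - item_id: '18'
      text: Question 18
      origin: panel_added
  - question_id: '19'
    text: Question 19
    response_format: likert_agreement
    items:
    - item_id: '19'
      text: Question 19
      origin: panel_added
  - question_id: '20'
    text: Question 20
    response_format: likert_agreement
    items:
    - item_id: '20'
      text: Question 20
      origin: panel_added
  - question_id: '21'
    text: Question 21
    response_format: likert_agreement
    items:
    - item_id: '21.1'
      text: Sub-item 1 of question 21
      origin: cp_fit
    - item_id: '21.2'
      text: Sub-item 2 of question 21
      origin: cp_fit
- part_id: part2_3
  title: Part 2_3
  ranking_depth: 5
  questions:
  - question_id: '22'
    text: Question 22
    response_format: likert_agreement
    items:
    - item_id: '22'
      text: Question 22
      origin: panel_added
  - question_id: '23'
    text: Question 23
    response_format: likert_agreement
    items:
    - item_id: '23.1'
      text: Sub-item 1 of question 23
      origin: cp_fit
    - item_id: '23.2'
      text: Sub-item 2 of question 23
      origin: cp_fit
    - item_id: '23.3'
      text: Sub-item 3 of question 23
      origin: cp_fit
    - item_id: '23.4'
      text: Sub-item 4 of question 23
      origin: cp_fit
    - item_id: '23.5'
      text: Sub-item 5 of question 23
      origin: cp_fit
    - item_id: '23.6'
      text: Sub-item 6 of question 23
      origin: cp_fit
    - item_id: '23.7'
      text: Sub-item 7 of question 23
      origin: cp_fit
    - item_id: '23.8'
      text: Sub-item 8 of question 23
      origin: cp_fit
  - question_id: '24'
    text: Question 24
    response_format: likert_agreement
    items:
    - item_id: '24.1'
      text: Sub-item 1 of question 24
      origin: cp_fit
    - item_id: '24.2'
      text: Sub-item 2 of question 24
      origin: cp_fit
  - question_id: '25'
    text: Question 25
    response_format: likert_agreement
    items:
    - item_id: '25'
      text: Question 25
      origin: panel_added
  - question_id: '26'
    text: Question 26
    response_format: likert_agreement
    items:
    - item_id: '26'
      text: Question 26
      origin: panel_added
- part_id: part2_4
  title: Part 2_4
  ranking_depth: 5
  questions:
  - question_id: '27'
    text: Question 27
    response_format: likert_agreement
    items:
    - item_id: '27.1'
      text: Sub-item 1 of question 27
      origin: cp_fit
    - item_id: '27.2'
      text: Sub-item 2 of question 27
      origin: cp_fit
    - item_id: '27.3'
      text: Sub-item 3 of question 27
      origin: cp_fit
    - item_id: '27.4'
      text: Sub-item 4 of question 27
      origin: cp_fit
    - item_id: '27.5'
      text: Sub-item 5 of question 27
      origin: cp_fit
    - item_id: '27.6'
      text: Sub-item 6 of question 27
      origin: cp_fit
    - item_id: '27.7'
      text: Sub-item 7 of question 27
      origin: cp_fit
    - item_id: '27.8'
      text: Sub-item 8 of question 27
      origin: cp_fit
    - item_id: '27.9'
      text: Sub-item 9 of question 27
      origin: cp_fit
  - question_id: '28'
    text: Question 28
    response_format: likert_agreement
    items:
    - item_id: '28'
      text: Question 28
      origin: panel_added
  - question_id: '29'
    text: Question 29
    response_format: likert_agreement
    items:
    - item_id: '29'
      text: Question 29
      origin: panel_added
  - question_id: '30'
    text: Question 30
    response_format: likert_agreement
    items:
    - item_id: '30'
      text: Question 30
      origin: panel_added
  - question_id: '31'
    text: Question 31
    response_format: likert_agreement
    items:
    - item_id: '31'
      text: Question 31
      origin: panel_added
  - question_id: '32'
    text: Question 32
    response_format: likert_agreement
    items:
    - item_id: '32'
      text: Question 32
      origin: panel_added
  - question_id: '33'
    text: Question 33
    response_format: likert_agreement
    items:
    - item_id: '33'
      text: Question 33
      origin: panel_added
  - question_id: '34'
    text: Question 34
    response_format: likert_agreement
    items:
    - item_id: '34'
      text: Question 34
      origin: panel_added
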