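# Default dialog script: tutorial offer -> interview -> confirmation ->
# search -> staged presentation (3 levels of detail, dictionary offers,
# bookmarking) -> refinement when results run out -> summary -> farewell.
# All agent copy here is original replacement text.
start: greet

facet_states:
  cancer_type: ask_cancer
  age: ask_age
  sex: ask_sex
  location: ask_location
  trial_type: ask_type
  phase: ask_phase
  investigational_drug_ok: ask_drug

templates:
  greet: "Hello {name}! I am Tanya. I can help you look for cancer clinical trials and explain anything you do not understand along the way. You never have to type - just pick one of the answers at the bottom of the screen."
  tutorial_offer: "Before we start, would you like me to explain what a clinical trial is and what taking part involves?"
  edu_voluntary: "A clinical trial is a research study with volunteers. Taking part is always voluntary - it is your choice, and you can change your mind and leave a study at any time without losing your regular care."
  edu_risk: "Studies can have risks as well as benefits. Every trial has a consent form that explains the possible risks, and the study staff must answer all of your questions before you join."
  ask_cancer: "Let us find trials that fit you. What kind of cancer are the trials for?"
  ask_age: "How old is the person the trial is for?"
  ask_sex: "Some trials are only for women or only for men. What should I look for?"
  ask_location: "Where should the trial be located?"
  ask_type: "What type of trial are you interested in? For example, treatment trials test new treatments, and prevention trials look at ways to stop cancer before it starts."
  ask_phase: "Trials happen in phases. Early phases test safety with small groups; later phases compare new treatments with standard ones. Do you want a particular phase?"
  ask_drug: "Some trials use experimental drugs that are still being tested. Would that be okay?"
  ask_pain: "Now a few questions about what you would be comfortable with, so I can show you the best matches first. Some studies involve procedures that can hurt, like biopsies. How do you feel about pain?"
  ask_invasiveness: "Some studies only ask questions, while others involve tests, scans, or operations. How invasive a study would be okay?"
  ask_time: "Studies ask for different amounts of your time - some are a single visit, others need visits every day. How much time could you give?"
  confirm: "Let me double-check what you are looking for. Here is what I have written down. Does it look right?"
  results_found: "Good news - there are {n} matching trials left for us to look at. Just say the word and I will tell you about them one at a time."
  results_none: "I could not find any more trials that match everything you asked for. We could loosen one of your requirements, or I can show you a summary of what we have seen."
  present1: "Here is a trial that matches your search. It is called {title}. This page shows who can join. Take your time."
  present2: "Here is more about this trial - this page adds what the researchers are hoping to learn."
  present3: "And this page adds what you would actually have to do in the study, step by step."
  dictionary: "Here are those medical words in plain language."
  summary: "Here are the trials we looked at today. The ones you asked me to save are marked."
  farewell: "Thanks for searching with me, {name}. Your saved trials will be here when you come back. Goodbye!"

states:
  greet:
    template: greet
    choices:
      - label: "Let's get started!"
        target: tutorial_offer
  tutorial_offer:
    template: tutorial_offer
    choices:
      - label: "Yes, please explain clinical trials first."
        call: education
        target: ask_cancer
      - label: "No thanks, I know about them. Let's search."
        target: ask_cancer
  ask_cancer:
    template: ask_cancer
    menu: {provider: facet, facet: cancer_type, next: ask_age, skip: "Any kind of cancer is okay."}
  ask_age:
    template: ask_age
    menu: {provider: facet, facet: age, next: ask_sex, skip: "I'd rather not say."}
  ask_sex:
    template: ask_sex
    menu: {provider: facet, facet: sex, next: ask_location, skip: "Show me trials for anyone."}
  ask_location:
    template: ask_location
    menu: {provider: facet, facet: location, next: ask_type, skip: "I'd rather not say."}
  ask_type:
    template: ask_type
    menu: {provider: facet, facet: trial_type, next: ask_phase, skip: "Any type is okay."}
  ask_phase:
    template: ask_phase
    menu: {provider: facet, facet: phase, next: ask_drug, skip: "Any phase is okay."}
  ask_drug:
    template: ask_drug
    menu: {provider: facet, facet: investigational_drug_ok, next: ask_pain, skip: "I'm not sure yet."}
  ask_pain:
    template: ask_pain
    menu: {provider: pref, criterion: pain, next: ask_invasiveness}
  ask_invasiveness:
    template: ask_invasiveness
    menu: {provider: pref, criterion: invasiveness, next: ask_time}
  ask_time:
    template: ask_time
    menu: {provider: pref, criterion: time_burden, next: confirm}
  confirm:
    template: confirm
    display: criteria
    menu: {provider: confirm, accept: results, accept_label: "That all looks right. Search for trials!"}
  results:
    template: results_found
    template_empty: results_none
    menu: {provider: results, present: present1, revise: confirm, summary: summary}
  present1:
    template: present1
    display: detail1
    on_enter: [view_current]
    menu: {provider: present, level: 1, more: present2, dictionary: dictionary, next: results}
  present2:
    template: present2
    display: detail2
    menu: {provider: present, level: 2, more: present3, dictionary: dictionary, next: confirm}
  present3:
    template: present3
    display: detail3
    menu: {provider: present, level: 3, dictionary: dictionary, again: present3, next: confirm}
  dictionary:
    template: dictionary
    display: dictionary
    choices:
      - label: "Thanks - let's keep going."
        target: "@return"
  summary:
    template: summary
    display: summary
    choices:
      - label: "Search again with the same criteria."
        target: results
        actions:
          - {type: run_search}
      - label: "Let me change my search criteria."
        target: confirm
      - label: "That's all for today. Goodbye!"
        target: farewell
  farewell:
    template: farewell
    terminal: true

subnetworks:
  education:
    start: edu_voluntary
    states:
      edu_voluntary:
        template: edu_voluntary
        choices:
          - label: "What about risks?"
            target: edu_risk
          - label: "Got it - let's move on."
            target: "@pop"
      edu_risk:
        template: edu_risk
        choices:
          - label: "Got it - let's move on."
            target: "@pop"
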