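term,definition
biopsy,taking a small piece of tissue from the body to look at under a microscope
surgery,an operation on the body
infusion,medicine given slowly into a vein through a tube
injection,medicine given with a needle
placebo,a treatment with no medicine in it used for comparison
metastatic,cancer that has spread to other parts of the body
endoscopy,looking inside the body with a thin tube that has a camera
transplant,replacing damaged cells or organs with healthy ones
resection,surgery to remove part of an organ or a tumor
imaging,pictures of the inside of the body such as x-rays or scans
protocol,the written plan a study follows
eligibility,the rules about who can join a study
chemotherapy,drugs that kill cancer cells
radiation,high-energy rays used to kill cancer cells
investigational drug,a drug that is still being tested and is not yet approved
consent form,the form that explains a study before you agree to join
remission,a time when cancer signs are reduced or gone
oncologist,a doctor who treats cancer
questionnaire,a written list of questions for you to answer
enrollment,officially joining a study
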