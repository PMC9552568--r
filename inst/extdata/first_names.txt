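JAMES
MARY
ROBERT
PATRICIA
JOHN
JENNIFER
MICHAEL
LINDA
DAVID
ELIZABETH
WILLIAM
BARBARA
RICHARD
SUSAN
JOSEPH
JESSICA
THOMAS
SARAH
CHARLES
KAREN
CHRISTOPHER
LISA
DANIEL
NANCY
MATTHEW
BETTY
ANTHONY
MARGARET
MARK
SANDRA
DONALD
ASHLEY
STEVEN
KIMBERLY
PAUL
EMILY
ANDREW
DONNA
JOSHUA
MICHELLE
KENNETH
CAROL
KEVIN
AMANDA
BRIAN
DOROTHY
GEORGE
MELISSA
TIMOTHY
DEBORAH
RONALD
STEPHANIE
EDWARD
REBECCA
JASON
SHARON
JEFFREY
LAURA
RYAN
CYNTHIA
JACOB
KATHLEEN
GARY
AMY
NICHOLAS
ANGELA
ERIC
SHIRLEY
JONATHAN
ANNA
STEPHEN
BRENDA
LARRY
PAMELA
JUSTIN
EMMA
SCOTT
NICOLE
BRANDON
HELEN
BENJAMIN
SAMANTHA
SAMUEL
KATHERINE
GREGORY
CHRISTINE
ALEXANDER
DEBRA
PATRICK
RACHEL
FRANK
CAROLYN
RAYMOND
JANET
JACK
MARIA
DENNIS
CATHERINE
JERRY
HEATHER
TYLER
DIANE
AARON
OLIVIA
JOSE
JULIE
ADAM
JOYCE
NATHAN
VICTORIA
HENRY
RUTH
ZACHARY
VIRGINIA
DOUGLAS
LAUREN
PETER
KELLY
KYLE
CHRISTINA
NOAH
JOAN
ETHAN
EVELYN
JEREMY
JUDITH
WALTER
ANDREA
CHRISTIAN
HANNAH
KEITH
MEGAN
ROGER
ALICE
TERRY
CHERYL
AUSTIN
JACQUELINE
SEAN
SOPHIA
GERALD
FRANCES
CARL
KATHRYN
DYLAN
TERESA
HAROLD
GLORIA
JORDAN
SARA
JESSE
JANICE
BRYAN
MARIE
LAWRENCE
MADISON
ARTHUR
GRACE
GABRIEL
DENISE
BRUCE
AMBER
LOGAN
DANIELLE
ALBERT
BRITTANY
WILLIE
ROSE
JUAN
DIANA
ELIJAH
NATALIE
WAYNE
ISABELLA
RANDY
ALEXIS
VINCENT
KAYLA
MASON
CHARLOTTE
ROY
LORI
RALPH
MONICA
BOBBY
TAMMY
RUSSELL
ERIN
BRADLEY
KRISTEN
PHILIP
COURTNEY
EUGENE
VANESSA
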